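#' Filter metabolites by missingness
#'
#' Excludes metabolites whose missing fraction reaches the threshold: a
#' metabolite is retained iff missing count / sample count is strictly below
#' \code{maxMissingFrac}. The default 0.10 excludes metabolites with >= 10%
#' missingness. Column order of retained metabolites is preserved.
#'
#' @param m A [MetaboliteMatrix-class].
#' @param maxMissingFrac fraction in [0, 1]; default 0.10.
#' @return list with elements \code{metabolites} (filtered
#'   [MetaboliteMatrix-class]) and \code{dropped} (character vector of
#'   excluded metabolite ids).
#' @export
filterMetaboliteMissingness <- function(m, maxMissingFrac = 0.10) {
  stopifnot(is(m, "MetaboliteMatrix"),
            maxMissingFrac >= 0, maxMissingFrac <= 1)
  a <- abundances(m)
  if (nrow(a) == 0L || ncol(a) == 0L)
    stop("filterMetaboliteMissingness: empty matrix")
  frac <- colMeans(is.na(a))
  keep <- frac < maxMissingFrac
  list(metabolites = metaboliteMatrix(a[, keep, drop = FALSE],
                                      analyteClass(m)[keep]),
       dropped = colnames(a)[!keep])
}

# Pairwise sample distances over shared observed metabolites:
#   d(a, b) = sqrt( sum_shared (x_a - x_b)^2 / n_shared )
# Computed by masked matrix products; Inf where no metabolite is shared.
.sharedDistances <- function(a) {
  W <- !is.na(a)
  X0 <- a
  X0[!W] <- 0
  S <- X0^2
  nShared <- tcrossprod(W * 1)
  D2 <- tcrossprod(S, W * 1) + tcrossprod(W * 1, S) - 2 * tcrossprod(X0)
  D2[D2 < 0] <- 0   # numerical guard
  d <- sqrt(D2 / nShared)
  d[nShared == 0] <- Inf
  d
}

#' K-nearest-neighbour imputation of missing metabolite values
#'
#' Each missing value is replaced by the unweighted mean of that metabolite
#' over the k nearest samples among those that observed it. Sample distance
#' is the Euclidean distance over metabolites observed in both samples,
#' scaled by the number of shared metabolites (so samples with different
#' missingness patterns are comparable). Running on a complete matrix is the
#' identity.
#'
#' @param m A [MetaboliteMatrix-class]; every sample must have at least one
#'   observed metabolite.
#' @param k positive integer, number of neighbours; must be smaller than the
#'   sample count. Default 5.
#' @return A complete [MetaboliteMatrix-class] (no missing values).
#' @export
knnImpute <- function(m, k = 5L) {
  stopifnot(is(m, "MetaboliteMatrix"), k >= 1L)
  a <- abundances(m)
  n <- nrow(a)
  if (k >= n) stop("knnImpute: k must be smaller than the sample count")
  if (!anyNA(a)) return(m)
  if (any(colSums(!is.na(a)) == 0L))
    stop("knnImpute: metabolite missing in all samples, cannot impute: ",
         paste(colnames(a)[colSums(!is.na(a)) == 0L], collapse = ", "))
  if (any(rowSums(!is.na(a)) == 0L))
    stop("knnImpute: sample with no observed metabolite")
  d <- .sharedDistances(a)
  diag(d) <- Inf
  out <- a
  for (j in which(colSums(is.na(a)) > 0L)) {
    donors <- which(!is.na(a[, j]))
    for (i in which(is.na(a[, j]))) {
      ord <- donors[order(d[i, donors], donors)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(a[nb, j])
    }
  }
  metaboliteMatrix(out, analyteClass(m))
}

#' Preprocess metabolite abundances for network integration
#'
#' The canonical metabolomics preprocessing chain: missingness filter
#' (default: exclude metabolites with >= 10% missingness), K-nearest-
#' neighbour imputation, per-metabolite Yeo-Johnson transformation fitted by
#' maximum likelihood, then centering to zero and scaling to unit variance.
#' Transform parameters are fitted on the pooled cohort by default; set
#' \code{stratum} to fit them per stratum instead.
#'
#' @param m A [MetaboliteMatrix-class].
#' @param maxMissingFrac missingness exclusion threshold, default 0.10.
#' @param k neighbours for imputation, default 5.
#' @param stratum optional logical vector (one per sample); when given, the
#'   transform/centering is fitted and applied within each stratum.
#' @return list: \code{matrix} (standardized numeric matrix, samples x
#'   retained metabolites), \code{params} (list of
#'   [YeoJohnsonParams-class] per metabolite, or per stratum-metabolite when
#'   stratified), \code{dropped} (excluded metabolite ids).
#' @export
preprocessMetabolites <- function(m, maxMissingFrac = 0.10, k = 5L,
                                  stratum = NULL) {
  filt <- filterMetaboliteMissingness(m, maxMissingFrac)
  imp <- knnImpute(filt$metabolites, k)
  a <- abundances(imp)
  out <- a
  if (is.null(stratum)) {
    params <- lapply(seq_len(ncol(a)), function(j) fitYeoJohnson(a[, j]))
    for (j in seq_len(ncol(a)))
      out[, j] <- applyYeoJohnson(a[, j], params[[j]])
    names(params) <- colnames(a)
  } else {
    stopifnot(length(stratum) == nrow(a))
    params <- list()
    for (g in unique(stratum)) {
      rows <- which(stratum == g)
      pg <- lapply(seq_len(ncol(a)), function(j) fitYeoJohnson(a[rows, j]))
      for (j in seq_len(ncol(a)))
        out[rows, j] <- applyYeoJohnson(a[rows, j], pg[[j]])
      names(pg) <- colnames(a)
      params[[as.character(g)]] <- pg
    }
  }
  list(matrix = out, params = params, dropped = filt$dropped)
}

#' Genotype quality control
#'
#' Retains a SNV iff its call rate is strictly above \code{minCallRate}, its
#' imputation-quality score (when present) is strictly above
#' \code{minQuality}, and its minor allele frequency is at least
#' \code{minMAF}. MAF is computed from dosages by default,
#' \code{min(p, 1 - p)} with \code{p = mean(dosage)/2} over non-missing
#' samples; \code{mafMethod = "hardcall"} rounds dosages to the nearest
#' genotype first.
#'
#' @param g A [GenotypeMatrix-class].
#' @param minCallRate default 0.95 (strict >).
#' @param minQuality default 0.95 (strict >; SNVs without a score pass).
#' @param minMAF default 0.05 (inclusive >=).
#' @param mafMethod "dosage" (default) or "hardcall".
#' @return list: \code{genotypes} (filtered [GenotypeMatrix-class]),
#'   \code{dropped} (data.frame snv, reason).
#' @export
genotypeQC <- function(g, minCallRate = 0.95, minQuality = 0.95,
                       minMAF = 0.05, mafMethod = c("dosage", "hardcall")) {
  stopifnot(is(g, "GenotypeMatrix"),
            minCallRate >= 0, minCallRate <= 1,
            minQuality >= 0, minQuality <= 1,
            minMAF >= 0, minMAF <= 1)
  mafMethod <- match.arg(mafMethod)
  d <- dosages(g)
  info <- snvInfo(g)
  callRate <- colMeans(!is.na(d))
  dm <- if (mafMethod == "hardcall") hardCalls(d) else d
  p <- colMeans(dm, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  qual <- info$quality
  qualOK <- is.na(qual) | qual > minQuality
  keep <- callRate > minCallRate & qualOK & maf >= minMAF & !is.nan(maf)
  reason <- character(ncol(d))
  reason[!(callRate > minCallRate)] <- "call rate"
  reason[!qualOK] <- "quality"
  reason[!(maf >= minMAF) | is.nan(maf)] <- "MAF"
  dropped <- data.frame(snv = colnames(d)[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep))
    message("genotypeQC: no SNV passed the filters")
  kept <- genotypeMatrix(d[, keep, drop = FALSE],
                         info[keep, , drop = FALSE])
  list(genotypes = kept, dropped = dropped)
}

#' Round dosages to hard genotype calls
#'
#' @param d numeric dosage matrix or vector in [0, 2].
#' @return same shape, values in {0, 1, 2} (NA preserved).
#' @export
hardCalls <- function(d) {
  out <- round(d)
  out[out < 0] <- 0
  out[out > 2] <- 2
  out
}

#' Derive antidepressant response from depression-severity totals
#'
#' Responders show at least a 50% reduction in the clinician-rated
#' depression total (QIDS-C, range 0-27) from baseline to week 8:
#' \code{(baseline - week8)/baseline >= 0.5}.
#'
#' @param baseline integer vector of baseline totals in 0-27; must be > 0.
#' @param week8 integer vector of week-8 totals in 0-27.
#' @return logical vector, TRUE for responders.
#' @examples
#' deriveResponse(16, 8)   # TRUE: exactly 50% reduction
#' deriveResponse(16, 9)   # FALSE
#' @export
deriveResponse <- function(baseline, week8) {
  stopifnot(length(baseline) == length(week8))
  if (any(baseline < 0 | baseline > 27 | week8 < 0 | week8 > 27,
          na.rm = TRUE))
    stop("deriveResponse: totals must lie in 0-27")
  if (any(baseline == 0, na.rm = TRUE))
    stop("deriveResponse: baseline of 0 leaves the reduction undefined")
  (baseline - week8) / baseline >= 0.5
}

#' Validate a phenotype table
#'
#' Checks the per-sample phenotype data.frame used throughout the pipeline:
#' requires \code{sample_id} and a logical/0-1 \code{attempt} stratum flag;
#' depression totals, when present, must lie in 0-27. If \code{response} is
#' absent but both \code{baseline_qids} and \code{week8_qids} are present,
#' the responder flag is derived.
#'
#' @param pheno data.frame.
#' @return the validated (possibly augmented) data.frame.
#' @export
validatePhenotypes <- function(pheno) {
  stopifnot(is.data.frame(pheno))
  for (col in c("sample_id", "attempt"))
    if (is.null(pheno[[col]]))
      stop("phenotype table is missing required column '", col, "'")
  if (anyDuplicated(pheno$sample_id))
    stop("phenotype table has duplicated sample ids")
  pheno$attempt <- as.logical(pheno$attempt)
  if (anyNA(pheno$attempt))
    stop("phenotype column 'attempt' must be logical or 0/1 with no missing")
  for (col in c("baseline_qids", "week8_qids"))
    if (!is.null(pheno[[col]]) &&
        any(pheno[[col]] < 0 | pheno[[col]] > 27, na.rm = TRUE))
      stop("phenotype column '", col, "' must lie in 0-27")
  if (is.null(pheno$response) &&
      !is.null(pheno$baseline_qids) && !is.null(pheno$week8_qids))
    pheno$response <- deriveResponse(pheno$baseline_qids, pheno$week8_qids)
  if (!is.null(pheno$response)) pheno$response <- as.logical(pheno$response)
  pheno
}
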