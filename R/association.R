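#' Genotypic (2-df) chi-square association test for one SNV
#'
#' Pearson chi-square on the stratum-by-genotype contingency table built
#' from hard calls (dosages rounded to 0/1/2). Genotype classes with a zero
#' column total are dropped, so the degrees of freedom equal the number of
#' observed genotype classes minus one (2 df for a fully polymorphic
#' biallelic SNV). No continuity correction; the p-value comes from the
#' upper tail of the chi-square distribution.
#'
#' @param dosage numeric vector of dosages in [0, 2] (NA dropped pairwise).
#' @param stratum logical vector, TRUE = stratum A.
#' @return list: \code{counts} (2 x G table, strata x genotypes),
#'   \code{chisq}, \code{df}, \code{p}, \code{maf}.
#' @examples
#' d <- c(rep(0, 10), rep(1, 10), rep(1, 10), rep(2, 10))
#' s <- rep(c(TRUE, FALSE), each = 20)
#' genotypicChisq(d, s)   # chisq = 20, df = 2, p = exp(-10)
#' @export
genotypicChisq <- function(dosage, stratum) {
  stopifnot(length(dosage) == length(stratum))
  ok <- !is.na(dosage) & !is.na(stratum)
  g <- hardCalls(dosage[ok])
  s <- stratum[ok]
  if (!any(s) || all(s))
    stop("genotypicChisq: a stratum is empty after dropping missing values")
  tab <- table(factor(s, levels = c(TRUE, FALSE)),
               factor(g, levels = 0:2))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  p <- mean(g) / 2
  maf <- min(p, 1 - p)
  if (ncol(tab) == 1L) {
    warning("genotypicChisq: only one genotype class observed")
    return(list(counts = tab, chisq = 0, df = 0L, p = 1, maf = maf))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(counts = tab, chisq = unname(ct$statistic),
       df = as.integer(unname(ct$parameter)), p = unname(ct$p.value),
       maf = maf)
}

#' Screen all SNVs for association with the stratum flag
#'
#' Applies [genotypicChisq()] to every SNV in a [GenotypeMatrix-class].
#'
#' @param g A [GenotypeMatrix-class].
#' @param stratum logical vector aligned with the samples of \code{g}.
#' @return data.frame: snv, chrom, pos, gene, maf, chisq, df, p.
#' @export
snvAssociation <- function(g, stratum) {
  stopifnot(is(g, "GenotypeMatrix"), length(stratum) == nrow(dosages(g)))
  d <- dosages(g)
  info <- snvInfo(g)
  res <- lapply(seq_len(ncol(d)), function(j)
    suppressWarnings(genotypicChisq(d[, j], stratum)))
  data.frame(snv = info$snv, chrom = info$chrom, pos = info$pos,
             gene = info$gene,
             maf = vapply(res, `[[`, numeric(1), "maf"),
             chisq = vapply(res, `[[`, numeric(1), "chisq"),
             df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
             p = vapply(res, `[[`, numeric(1), "p"),
             stringsAsFactors = FALSE)
}

#' Select nominally significant candidate SNVs
#'
#' Retains SNVs with p <= alpha (inclusive threshold), sorted ascending by
#' p-value (ties stable in input order).
#'
#' @param results data.frame from [snvAssociation()] (needs snv, p).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return character vector of selected SNV ids.
#' @export
selectCandidates <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (nrow(results) == 0L) return(character())
  hit <- results[results$p <= alpha, , drop = FALSE]
  hit$snv[order(hit$p)]
}

#' Greedy linkage-disequilibrium pruning
#'
#' Visits SNVs in ascending p-value order (ties broken by chromosome then
#' position) and keeps a SNV iff its squared Pearson dosage correlation with
#' every already-kept SNV on the same chromosome is at most
#' \code{r2Threshold}. This is composite (phase-free) LD, appropriate for
#' dosage data. The result is fully determined by (p, chromosome, position),
#' independent of input row order.
#'
#' @param g A [GenotypeMatrix-class].
#' @param results association data.frame covering all SNVs of \code{g}
#'   (columns snv, p).
#' @param r2Threshold default 0.8.
#' @return character vector of kept SNV ids (in visit order).
#' @export
ldPrune <- function(g, results, r2Threshold = 0.8) {
  stopifnot(is(g, "GenotypeMatrix"),
            r2Threshold >= 0, r2Threshold <= 1)
  d <- dosages(g)
  info <- snvInfo(g)
  if (!all(colnames(d) %in% results$snv))
    stop("ldPrune: results must cover all SNVs in the genotype matrix")
  p <- results$p[match(colnames(d), results$snv)]
  ord <- order(p, info$chrom, info$pos)
  kept <- integer()
  for (j in ord) {
    same <- kept[info$chrom[kept] == info$chrom[j]]
    ok <- TRUE
    for (k in same) {
      r <- suppressWarnings(
        stats::cor(d[, j], d[, k], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2Threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  colnames(d)[kept]
}

#' Stratum comparison statistics for a cohort characteristic
#'
#' The standard demographics-table tests: two-sided two-sample t-test for
#' continuous variables (Welch by default), Fisher's exact test (two-sided,
#' probability-at-most-observed rule) for categorical variables, and the
#' Kruskal-Wallis rank test (with tie correction) for ordinal variables.
#'
#' @param values per-sample vector (numeric for continuous/ordinal; anything
#'   coercible to factor for categorical).
#' @param kind "continuous", "categorical" or "ordinal".
#' @param stratum logical vector, TRUE = stratum A; both strata must be
#'   non-empty.
#' @param pooled logical; use the pooled-variance t-test instead of Welch.
#' @return list: \code{statistic}, \code{p.value}, \code{method}.
#' @export
cohortCompare <- function(values,
                          kind = c("continuous", "categorical", "ordinal"),
                          stratum, pooled = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(stratum))
  ok <- !is.na(values) & !is.na(stratum)
  values <- values[ok]
  stratum <- stratum[ok]
  if (!any(stratum) || all(stratum))
    stop("cohortCompare: both strata must be non-empty")
  if (kind != "categorical" && length(unique(values)) < 2L) {
    warning("cohortCompare: degenerate (constant) values, p = 1")
    return(list(statistic = 0, p.value = 1, method = "degenerate"))
  }
  if (kind == "continuous") {
    tt <- stats::t.test(values[stratum], values[!stratum],
                        var.equal = pooled)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         method = tt$method)
  } else if (kind == "ordinal") {
    kw <- stats::kruskal.test(values, factor(stratum))
    list(statistic = unname(kw$statistic), p.value = kw$p.value,
         method = kw$method)
  } else {
    tab <- table(factor(stratum, levels = c(TRUE, FALSE)), values)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L) {
      warning("cohortCompare: degenerate (constant) values, p = 1")
      return(list(statistic = 0, p.value = 1, method = "degenerate"))
    }
    ft <- tryCatch(stats::fisher.test(tab),
                   error = function(e)
                     suppressWarnings(stats::chisq.test(tab,
                                                        correct = FALSE)))
    list(statistic = if (!is.null(ft$estimate)) unname(ft$estimate) else
           unname(ft$statistic),
         p.value = ft$p.value, method = ft$method)
  }
}
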