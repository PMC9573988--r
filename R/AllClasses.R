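#' @import methods
NULL

.ANALYTE_CLASSES <- c("acylcarnitine", "amino acid", "biogenic amine",
                      "glycerophospholipid", "sphingolipid", "other")

#' GenotypeMatrix: samples-by-SNV additive dosages
#'
#' Container for biallelic single nucleotide variant (SNV) dosages, the count
#' of alternate alleles per sample (0, 1 or 2 copies; fractional dosages from
#' imputation are allowed). Rows are samples, columns SNVs. Per-SNV metadata
#' (chromosome, 1-based position, ref/alt alleles, nearest-gene label and an
#' optional imputation-quality score) lives in \code{snvInfo}.
#'
#' @slot dosage numeric matrix, samples x SNVs, values in [0, 2] or NA.
#' @slot snvInfo data.frame with one row per SNV: \code{snv}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{gene}, \code{quality}.
#'
#' @seealso [genotypeMatrix()], [dosages()], [snvInfo()], [genotypeQC()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(dosage = "matrix", snvInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  info <- object@snvInfo
  msgs <- character()
  if ((nrow(d) > 0 && is.null(rownames(d))) ||
      (ncol(d) > 0 && is.null(colnames(d))))
    msgs <- c(msgs, "dosage matrix must have sample rownames and SNV colnames")
  else {
    if (anyDuplicated(rownames(d))) msgs <- c(msgs, "duplicated sample ids")
    if (anyDuplicated(colnames(d))) msgs <- c(msgs, "duplicated SNV ids")
  }
  need <- c("snv", "chrom", "pos", "ref", "alt", "gene", "quality")
  if (!all(need %in% names(info)))
    msgs <- c(msgs, paste("snvInfo must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(info) != ncol(d) ||
        (ncol(d) > 0 && !identical(info$snv, colnames(d))))
      msgs <- c(msgs, "snvInfo rows must match dosage columns (same order)")
    if (any(info$pos <= 0)) msgs <- c(msgs, "positions must be positive")
  }
  if (length(d) && !all(is.na(d))) {
    rng <- range(d, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      msgs <- c(msgs, "dosages must lie in [0, 2] where present")
  }
  if (length(msgs)) msgs else TRUE
})

#' MetaboliteMatrix: samples-by-metabolite abundances
#'
#' Container for a targeted metabolomics abundance table (e.g. a p180-style
#' panel). Rows are samples, columns metabolites; missing measurements are NA.
#' Each metabolite carries an analyte-class label (acylcarnitine, amino acid,
#' biogenic amine, glycerophospholipid, sphingolipid, or other).
#'
#' @slot abundance numeric matrix, samples x metabolites, NA allowed.
#' @slot analyteClass character vector, one class label per metabolite.
#'
#' @seealso [metaboliteMatrix()], [abundances()], [analyteClass()],
#'   [preprocessMetabolites()]
#' @exportClass MetaboliteMatrix
setClass("MetaboliteMatrix",
         representation(abundance = "matrix", analyteClass = "character"))

setValidity("MetaboliteMatrix", function(object) {
  a <- object@abundance
  msgs <- character()
  if ((nrow(a) > 0 && is.null(rownames(a))) ||
      (ncol(a) > 0 && is.null(colnames(a))))
    msgs <- c(msgs, "abundance matrix must have sample rownames and metabolite colnames")
  else {
    if (anyDuplicated(rownames(a))) msgs <- c(msgs, "duplicated sample ids")
    if (anyDuplicated(colnames(a))) msgs <- c(msgs, "duplicated metabolite ids")
  }
  if (length(object@analyteClass) != ncol(a))
    msgs <- c(msgs, "analyteClass length must equal number of metabolites")
  if (any(is.infinite(a)))
    msgs <- c(msgs, "abundances must be finite or NA")
  if (length(msgs)) msgs else TRUE
})

#' YeoJohnsonParams: fitted power-transform parameters for one variable
#'
#' Holds the maximum-likelihood Yeo-Johnson power parameter lambda together
#' with the post-transform centering (mean) and scaling (standard deviation)
#' constants, so that applying the parameters standardizes new data to the
#' training scale.
#'
#' @slot lambda numeric(1), power parameter (dimensionless), finite.
#' @slot center numeric(1), mean of the transformed training values.
#' @slot scale numeric(1), standard deviation of the transformed training
#'   values; strictly positive.
#'
#' @seealso [fitYeoJohnson()], [applyYeoJohnson()], [yeoJohnson()]
#' @exportClass YeoJohnsonParams
setClass("YeoJohnsonParams",
         representation(lambda = "numeric", center = "numeric",
                        scale = "numeric"))

setValidity("YeoJohnsonParams", function(object) {
  msgs <- character()
  if (length(object@lambda) != 1L || !is.finite(object@lambda))
    msgs <- c(msgs, "lambda must be a single finite number")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msgs <- c(msgs, "scale must be a single positive number")
  if (length(object@center) != 1L || !is.finite(object@center))
    msgs <- c(msgs, "center must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' PLSFit: a fitted (sparse) partial least squares model
#'
#' Result of the NIPALS-style sequential PLS fit between two feature blocks.
#' Latent score vectors are mutually orthogonal; optional per-component hard
#' sparsity (keepX/keepY) zeroes all but the largest-magnitude weight entries
#' before normalization.
#'
#' @slot scores numeric matrix n x H of latent score vectors t_h.
#' @slot xWeights,yWeights weight vectors per component (p x H, q x H).
#' @slot xLoadings,yLoadings regression loadings used for deflation.
#' @slot ncomp integer, number of fitted components H.
#' @slot keepX,keepY integer vectors of kept-variable counts per component.
#'
#' @seealso [plsFit()], [similarityMatrix()]
#' @exportClass PLSFit
setClass("PLSFit",
         representation(scores = "matrix", xWeights = "matrix",
                        yWeights = "matrix", xLoadings = "matrix",
                        yLoadings = "matrix", ncomp = "integer",
                        keepX = "integer", keepY = "integer"))

setValidity("PLSFit", function(object) {
  msgs <- character()
  H <- object@ncomp
  if (ncol(object@scores) != H)
    msgs <- c(msgs, "scores must have ncomp columns")
  if (H > 1) {
    G <- crossprod(object@scores)
    off <- max(abs(G[upper.tri(G)]))
    scl <- max(diag(G))
    if (off > 1e-6 * max(scl, 1))
      msgs <- c(msgs, "score vectors must be pairwise orthogonal")
  }
  if (length(msgs)) msgs else TRUE
})

#' OmicsNetwork: a thresholded multi-block association network
#'
#' Nodes are features typed by block (snv, metabolite, outcome); edges carry
#' the signed PLS component similarity s in [-1, 1] and its correlation-test
#' p-value. Only features with at least one retained edge enter the network.
#' Community labels come from weighted Louvain modularity optimization on
#' absolute weights; eigenvector centrality is max-normalized to 1.
#'
#' @slot nodes data.frame: \code{feature}, \code{block}, \code{community}
#'   (integer, 0-based, decreasing community size), \code{centrality}.
#' @slot edges data.frame: \code{from}, \code{to}, \code{weight} (signed s),
#'   \code{p}.
#' @slot n integer, number of samples the similarities were estimated from.
#' @slot config list, the NetworkConfig used to build the network.
#'
#' @seealso [buildNetwork()], [networkConfig()], [deltaCentrality()]
#' @exportClass OmicsNetwork
setClass("OmicsNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        n = "integer", config = "list"))

setValidity("OmicsNetwork", function(object) {
  msgs <- character()
  nn <- c("feature", "block", "community", "centrality")
  if (!all(nn %in% names(object@nodes)))
    msgs <- c(msgs, paste("nodes needs columns:", paste(nn, collapse = ", ")))
  en <- c("from", "to", "weight", "p")
  if (!all(en %in% names(object@edges)))
    msgs <- c(msgs, paste("edges needs columns:", paste(en, collapse = ", ")))
  if (nrow(object@nodes)) {
    cen <- object@nodes$centrality
    if (any(cen < -1e-12 | cen > 1 + 1e-12))
      msgs <- c(msgs, "centralities must lie in [0, 1]")
    if (abs(max(cen) - 1) > 1e-8)
      msgs <- c(msgs, "maximum centrality must be 1 on non-empty networks")
  }
  if (nrow(object@edges)) {
    if (any(abs(object@edges$weight) > 1 + 1e-12))
      msgs <- c(msgs, "edge weights must lie in [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: synthetic cohort generator configuration
#'
#' Describes a two-stratum cohort (stratum A: lifetime history of suicide
#' attempt; stratum B: no history) with biallelic SNVs, metabolites in
#' correlated analyte-class blocks, planted group-specific SNV-to-metabolite
#' linear effects, and a binary treatment response linked to metabolites.
#' Defaults emulate the study design this package targets: 46 vs 302
#' participants, candidate SNVs with MAF at or above 0.05, 153 metabolites in
#' five analyte-class blocks, response rate about two thirds.
#'
#' @slot nPerGroup integer(2): samples in stratum A ("attempt") and B
#'   ("no attempt").
#' @slot nSnvs integer(1): number of simulated SNVs.
#' @slot mafRange numeric(2): minor-allele-frequency range, within (0, 0.5].
#' @slot snvMaf numeric: optional fixed per-SNV MAF (length nSnvs, or empty to
#'   draw uniformly from mafRange).
#' @slot assocSnvs data.frame (\code{snv}, \code{mafA}, \code{mafB}): SNVs
#'   whose MAF differs by stratum, planting a genotype-stratum association.
#' @slot nMetabolites integer(1).
#' @slot classBlocks data.frame (\code{name}, \code{size}, \code{rho}):
#'   analyte-class blocks; sizes must sum to nMetabolites; rho in [0, 1) is
#'   the exchangeable within-block correlation.
#' @slot plantedEffects data.frame (\code{snv}, \code{metabolite},
#'   \code{beta}, \code{group}): linear dosage effects (standardized-units
#'   slope per allele copy) active in group "A", "B" or "both".
#' @slot responseModel data.frame (\code{metabolite}, \code{coef},
#'   \code{group}): logistic log-odds coefficients linking metabolites to the
#'   binary treatment response, active per group.
#' @slot responseRate numeric(1): target marginal response rate; the logistic
#'   intercept is solved by 1-D root finding to hit it.
#' @slot duplicateSnvs data.frame (\code{from}, \code{to}): SNVs copied
#'   verbatim from another SNV, creating perfect-linkage pairs for prune
#'   testing.
#' @slot missingRate numeric(1): metabolite missing-completely-at-random rate
#'   in [0, 0.5).
#' @slot seed integer(1).
#'
#' @seealso [simConfig()], [generateCohort()]
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nPerGroup = "integer", nSnvs = "integer",
                        mafRange = "numeric", snvMaf = "numeric",
                        assocSnvs = "data.frame", nMetabolites = "integer",
                        classBlocks = "data.frame",
                        plantedEffects = "data.frame",
                        responseModel = "data.frame",
                        responseRate = "numeric",
                        duplicateSnvs = "data.frame",
                        missingRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  bad <- function(m) msgs <<- c(msgs, m)
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 1L))
    bad("nPerGroup must be two positive integers")
  if (object@nSnvs < 1L) bad("nSnvs must be positive")
  if (object@nMetabolites < 1L) bad("nMetabolites must be positive")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    bad("mafRange must lie within (0, 0.5]")
  if (length(object@snvMaf) &&
      (length(object@snvMaf) != object@nSnvs ||
       any(object@snvMaf <= 0 | object@snvMaf > 0.5)))
    bad("snvMaf must have length nSnvs with values in (0, 0.5]")
  cb <- object@classBlocks
  if (!all(c("name", "size", "rho") %in% names(cb)))
    bad("classBlocks needs columns name, size, rho")
  else {
    if (sum(cb$size) != object@nMetabolites)
      bad("classBlocks sizes must sum to nMetabolites")
    if (any(cb$rho < 0 | cb$rho >= 1))
      bad("classBlocks rho must lie in [0, 1)")
  }
  pe <- object@plantedEffects
  if (!all(c("snv", "metabolite", "beta", "group") %in% names(pe)))
    bad("plantedEffects needs columns snv, metabolite, beta, group")
  else if (nrow(pe)) {
    if (any(pe$snv < 1 | pe$snv > object@nSnvs))
      bad("plantedEffects snv index out of range")
    if (any(pe$metabolite < 1 | pe$metabolite > object@nMetabolites))
      bad("plantedEffects metabolite index out of range")
    if (any(!is.finite(pe$beta))) bad("plantedEffects beta must be finite")
    if (any(!pe$group %in% c("A", "B", "both")))
      bad("plantedEffects group must be one of A, B, both")
  }
  rm_ <- object@responseModel
  if (!all(c("metabolite", "coef", "group") %in% names(rm_)))
    bad("responseModel needs columns metabolite, coef, group")
  else if (nrow(rm_)) {
    if (any(rm_$metabolite < 1 | rm_$metabolite > object@nMetabolites))
      bad("responseModel metabolite index out of range")
    if (any(!rm_$group %in% c("A", "B", "both")))
      bad("responseModel group must be one of A, B, both")
  }
  if (object@missingRate < 0 || object@missingRate >= 0.5)
    bad("missingRate must lie in [0, 0.5)")
  if (object@responseRate <= 0 || object@responseRate >= 1)
    bad("responseRate must lie in (0, 1)")
  du <- object@duplicateSnvs
  if (nrow(du) && any(du$from < 1 | du$from > object@nSnvs |
                      du$to < 1 | du$to > object@nSnvs))
    bad("duplicateSnvs indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' SimTruth: ground-truth registry for a simulated cohort
#'
#' Records everything planted by [generateCohort()] so downstream stages can
#' be scored: the realized group-specific effects, per-SNV true MAF (per
#' stratum), the metabolite-response links, and the seed.
#'
#' @slot effects data.frame: realized planted effects with resolved feature
#'   ids (\code{snv}, \code{metabolite}, \code{snvId}, \code{metaboliteId},
#'   \code{beta}, \code{group}).
#' @slot maf data.frame: per-SNV true MAF in each stratum (\code{snv},
#'   \code{mafA}, \code{mafB}).
#' @slot responseLinks data.frame: \code{metabolite}, \code{metaboliteId},
#'   \code{coef}, \code{group}, plus the solved logistic \code{intercept} as
#'   an attribute-free extra column.
#' @slot seed integer(1).
#'
#' @seealso [generateCohort()], [scoreRecovery()]
#' @exportClass SimTruth
setClass("SimTruth",
         representation(effects = "data.frame", maf = "data.frame",
                        responseLinks = "data.frame", seed = "integer"))
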