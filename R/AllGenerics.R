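#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix (samples x SNVs) of alternate-allele dosages
#'   in [0, 2]; NA for missing. Must carry rownames (sample ids) and colnames
#'   (SNV ids).
#' @param snvInfo optional data.frame of per-SNV metadata (columns snv, chrom,
#'   pos, ref, alt, gene, quality); defaults are filled for absent columns.
#' @return A [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(dosage, snvInfo = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(snvInfo)) {
    snvInfo <- data.frame(snv = colnames(dosage), stringsAsFactors = FALSE)
  }
  snvInfo <- as.data.frame(snvInfo, stringsAsFactors = FALSE)
  if (is.null(snvInfo$snv)) snvInfo$snv <- colnames(dosage)
  p <- nrow(snvInfo)
  if (is.null(snvInfo$chrom)) snvInfo$chrom <- rep("1", p)
  if (is.null(snvInfo$pos)) snvInfo$pos <- seq_len(p)
  if (is.null(snvInfo$ref)) snvInfo$ref <- rep("A", p)
  if (is.null(snvInfo$alt)) snvInfo$alt <- rep("G", p)
  if (is.null(snvInfo$gene)) snvInfo$gene <- rep(NA_character_, p)
  if (is.null(snvInfo$quality)) snvInfo$quality <- rep(NA_real_, p)
  snvInfo <- snvInfo[c("snv", "chrom", "pos", "ref", "alt", "gene", "quality")]
  rownames(snvInfo) <- NULL
  new("GenotypeMatrix", dosage = dosage, snvInfo = snvInfo)
}

#' Construct a MetaboliteMatrix
#'
#' @param abundance numeric matrix (samples x metabolites), NA for missing;
#'   must carry rownames (sample ids) and colnames (metabolite ids).
#' @param analyteClass character vector of per-metabolite analyte-class
#'   labels; recycled "other" when omitted.
#' @return A [MetaboliteMatrix-class] object.
#' @export
metaboliteMatrix <- function(abundance, analyteClass = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(analyteClass)) analyteClass <- rep("other", ncol(abundance))
  new("MetaboliteMatrix", abundance = abundance,
      analyteClass = as.character(analyteClass))
}

#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Access the dosage matrix of a GenotypeMatrix
#'
#' @param x A [GenotypeMatrix-class].
#' @return The samples x SNVs numeric dosage matrix.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname snvInfo
#' @export
setGeneric("snvInfo", function(x) standardGeneric("snvInfo"))

#' Access per-SNV metadata
#'
#' @param x A [GenotypeMatrix-class].
#' @return data.frame with columns snv, chrom, pos, ref, alt, gene, quality.
#' @export
setMethod("snvInfo", "GenotypeMatrix", function(x) x@snvInfo)

#' @rdname abundances
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' Access the abundance matrix of a MetaboliteMatrix
#'
#' @param x A [MetaboliteMatrix-class].
#' @return The samples x metabolites numeric matrix (NA = missing).
#' @export
setMethod("abundances", "MetaboliteMatrix", function(x) x@abundance)

#' @rdname analyteClass
#' @export
setGeneric("analyteClass", function(x) standardGeneric("analyteClass"))

#' Access per-metabolite analyte-class labels
#'
#' @param x A [MetaboliteMatrix-class].
#' @return character vector of class labels, one per metabolite.
#' @export
setMethod("analyteClass", "MetaboliteMatrix", function(x) x@analyteClass)

#' @rdname missingnessMask
#' @export
setGeneric("missingnessMask", function(x) standardGeneric("missingnessMask"))

#' Logical missingness mask of a MetaboliteMatrix
#'
#' @param x A [MetaboliteMatrix-class].
#' @return logical matrix, TRUE where the measurement is missing.
#' @export
setMethod("missingnessMask", "MetaboliteMatrix",
          function(x) is.na(x@abundance))

#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Sample identifiers
#'
#' @param x A [GenotypeMatrix-class] or [MetaboliteMatrix-class].
#' @return character vector of sample ids (matrix rownames).
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "MetaboliteMatrix", function(x) rownames(x@abundance))

#' @rdname netNodes
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))

#' Node table of an OmicsNetwork
#'
#' @param x An [OmicsNetwork-class].
#' @return data.frame: feature, block, community (0-based), centrality.
#' @export
setMethod("netNodes", "OmicsNetwork", function(x) x@nodes)

#' @rdname netEdges
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' Edge table of an OmicsNetwork
#'
#' @param x An [OmicsNetwork-class].
#' @return data.frame: from, to, weight (signed similarity), p.
#' @export
setMethod("netEdges", "OmicsNetwork", function(x) x@edges)

#' @rdname sampleSize
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' Number of samples behind a network's similarities
#'
#' @param x An [OmicsNetwork-class].
#' @return integer sample count used for edge significance.
#' @export
setMethod("sampleSize", "OmicsNetwork", function(x) x@n)

#' @rdname plsScores
#' @export
setGeneric("plsScores", function(x) standardGeneric("plsScores"))

#' Latent score matrix of a PLSFit
#'
#' @param x A [PLSFit-class].
#' @return n x H matrix of mutually orthogonal latent scores.
#' @export
setMethod("plsScores", "PLSFit", function(x) x@scores)

#' @rdname truthEffects
#' @export
setGeneric("truthEffects", function(x) standardGeneric("truthEffects"))

#' Planted effect registry of a SimTruth
#'
#' @param x A [SimTruth-class].
#' @return data.frame of realized planted SNV-to-metabolite effects.
#' @export
setMethod("truthEffects", "SimTruth", function(x) x@effects)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat("GenotypeMatrix:", nrow(d), "samples x", ncol(d), "SNVs\n")
  cat("  missing dosages:", sum(is.na(d)), "\n")
  chr <- unique(object@snvInfo$chrom)
  cat("  chromosomes:", paste(utils::head(chr, 8), collapse = ", "),
      if (length(chr) > 8) "..." else "", "\n")
})

setMethod("show", "MetaboliteMatrix", function(object) {
  a <- object@abundance
  cat("MetaboliteMatrix:", nrow(a), "samples x", ncol(a), "metabolites\n")
  cat("  missingness:",
      sprintf("%.3f%%", 100 * mean(is.na(a))), "\n")
  cat("  analyte classes:",
      paste(names(table(object@analyteClass)), collapse = ", "), "\n")
})

setMethod("show", "YeoJohnsonParams", function(object) {
  cat(sprintf("YeoJohnsonParams: lambda=%.4f center=%.4g scale=%.4g\n",
              object@lambda, object@center, object@scale))
})

setMethod("show", "PLSFit", function(object) {
  cat("PLSFit:", object@ncomp, "components,",
      nrow(object@scores), "samples;",
      nrow(object@xWeights), "X-features,",
      nrow(object@yWeights), "Y-features\n")
})

setMethod("show", "OmicsNetwork", function(object) {
  cat("OmicsNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (n =", object@n, "samples)\n")
  if (nrow(object@nodes)) {
    cat("  blocks:", paste(sprintf("%s=%d", names(table(object@nodes$block)),
                                   table(object@nodes$block)),
                           collapse = ", "), "\n")
    cat("  communities:", length(unique(object@nodes$community)), "\n")
  }
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", sum(object@nPerGroup), "samples (A =",
      object@nPerGroup[1], ", B =", object@nPerGroup[2], "),",
      object@nSnvs, "SNVs,", object@nMetabolites, "metabolites\n")
  cat("  planted effects:", nrow(object@plantedEffects),
      "| response links:", nrow(object@responseModel),
      "| seed:", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@effects), "planted effects,",
      nrow(object@responseLinks), "response links (seed",
      object@seed, ")\n")
})
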