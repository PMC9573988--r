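#' Pipeline run configuration
#'
#' Houses every threshold of the end-to-end analysis: metabolite
#' missingness exclusion (0.10), genotype call rate (0.95) and imputation
#' quality (0.95), MAF (0.05), association alpha (0.05), LD pruning r^2
#' (0.8), KNN imputation k (5), the network configuration, and the global
#' seed.
#'
#' @param vcf,metabolites,phenotypes input file paths.
#' @param outDir output directory.
#' @param maxMissingFrac,minCallRate,minQuality,minMAF,alpha,ldR2,knnK
#'   thresholds (defaults above).
#' @param network list from [networkConfig()].
#' @param stratumColumn,responseColumn phenotype column names, defaults
#'   "attempt" and "response".
#' @param seed global integer seed.
#' @return a named configuration list for [runPipeline()].
#' @export
runConfig <- function(vcf, metabolites, phenotypes, outDir,
                      maxMissingFrac = 0.10, minCallRate = 0.95,
                      minQuality = 0.95, minMAF = 0.05, alpha = 0.05,
                      ldR2 = 0.8, knnK = 5L, network = networkConfig(),
                      stratumColumn = "attempt",
                      responseColumn = "response", seed = 1L) {
  stopifnot(maxMissingFrac >= 0, maxMissingFrac <= 1,
            minCallRate >= 0, minCallRate <= 1,
            minMAF >= 0, minMAF <= 1, alpha > 0, alpha < 1,
            ldR2 >= 0, ldR2 <= 1, knnK >= 1)
  list(vcf = vcf, metabolites = metabolites, phenotypes = phenotypes,
       outDir = outDir, maxMissingFrac = maxMissingFrac,
       minCallRate = minCallRate, minQuality = minQuality,
       minMAF = minMAF, alpha = alpha, ldR2 = ldR2,
       knnK = as.integer(knnK), network = network,
       stratumColumn = stratumColumn, responseColumn = responseColumn,
       seed = as.integer(seed))
}

.stageLog <- function(stage, seed, ...) {
  message(sprintf("[%s] (seed %d) ", stage, seed), ...)
}

#' Stratified network analysis of preprocessed cohort data
#'
#' The analysis core shared by [runPipeline()] and the benchmarks: builds
#' one association network per stratum from the SNV, metabolite and outcome
#' blocks (network B omits the outcome block when the response carries no
#' variation there), then computes the delta-centrality table and the edge
#' diff.
#'
#' @param dosage numeric dosage matrix (samples x SNVs) restricted to the
#'   SNVs entering the networks; no missing values (complete hard calls or
#'   imputed dosages).
#' @param metabolites standardized metabolite matrix (samples x
#'   metabolites).
#' @param response logical or 0/1 response vector.
#' @param stratum logical vector, TRUE = stratum A.
#' @param network list from [networkConfig()].
#' @return list: \code{netA}, \code{netB}, \code{delta}, \code{diff}.
#' @export
stratifiedNetworks <- function(dosage, metabolites, response, stratum,
                               network = networkConfig()) {
  stopifnot(nrow(dosage) == length(stratum),
            nrow(metabolites) == length(stratum),
            length(response) == length(stratum))
  buildOne <- function(rows) {
    blocks <- list(snv = dosage[rows, , drop = FALSE],
                   metabolite = metabolites[rows, , drop = FALSE])
    resp <- as.numeric(response[rows])
    if (length(unique(resp[!is.na(resp)])) > 1L && !anyNA(resp)) {
      blocks$outcome <- matrix(resp, ncol = 1,
                               dimnames = list(rownames(dosage)[rows],
                                               "response"))
    }
    suppressWarnings(buildNetwork(blocks, network))
  }
  netA <- buildOne(which(stratum))
  netB <- buildOne(which(!stratum))
  delta <- suppressWarnings(deltaCentrality(netA, netB))
  list(netA = netA, netB = netB, delta = delta,
       diff = edgeDiff(netA, netB))
}

#' Run the full integrative analysis pipeline
#'
#' Executes read, QC/preprocessing, the genotypic chi-square screen, LD
#' pruning, per-stratum PLS network construction, and delta-centrality
#' ranking, writing every artifact plus a manifest JSON with MD5 checksums.
#' With a fixed seed the manifest checksums are identical across runs.
#'
#' @param cfg configuration list from [runConfig()] or [readRunConfig()].
#' @return invisibly, the manifest as a list (artifact paths, checksums,
#'   stage summaries).
#' @export
runPipeline <- function(cfg) {
  seed <- cfg$seed
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  .stageLog("read", seed, "loading inputs")
  geno <- readGenotypesVCF(cfg$vcf)
  met <- readMetabolitesCSV(cfg$metabolites)
  pheno <- readPhenotypesCSV(cfg$phenotypes)
  if (!cfg$stratumColumn %in% names(pheno))
    stop("runPipeline[read]: phenotype table is missing the stratum column '",
         cfg$stratumColumn, "'")

  shared <- Reduce(intersect, list(sampleIds(geno), sampleIds(met),
                                   pheno$sample_id))
  if (length(shared) == 0L)
    stop("runPipeline[read]: sample-id intersection of the three inputs is empty")
  .stageLog("read", seed, length(shared), " shared samples")
  geno <- genotypeMatrix(dosages(geno)[shared, , drop = FALSE], snvInfo(geno))
  met <- metaboliteMatrix(abundances(met)[shared, , drop = FALSE],
                          analyteClass(met))
  pheno <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  stratum <- as.logical(pheno[[cfg$stratumColumn]])
  if (is.null(pheno[[cfg$responseColumn]]))
    stop("runPipeline[read]: phenotype table is missing the response column '",
         cfg$responseColumn, "'")
  response <- as.logical(pheno[[cfg$responseColumn]])

  .stageLog("qc", seed, "genotype and metabolite QC")
  gqc <- genotypeQC(geno, cfg$minCallRate, cfg$minQuality, cfg$minMAF)
  prep <- preprocessMetabolites(met, cfg$maxMissingFrac, cfg$knnK)

  .stageLog("associate", seed, "genotypic chi-square screen")
  assoc <- snvAssociation(gqc$genotypes, stratum)
  candidates <- selectCandidates(assoc, cfg$alpha)
  .stageLog("associate", seed, length(candidates), " candidate SNV(s)")

  .stageLog("prune", seed, "LD pruning at r2 <= ", cfg$ldR2)
  kept <- character()
  if (length(candidates)) {
    candGeno <- genotypeMatrix(
      dosages(gqc$genotypes)[, candidates, drop = FALSE],
      snvInfo(gqc$genotypes)[match(candidates,
                                   snvInfo(gqc$genotypes)$snv), ,
                             drop = FALSE])
    kept <- ldPrune(candGeno, assoc, cfg$ldR2)
  }
  assoc$selected <- assoc$snv %in% candidates
  assoc$pruned <- assoc$selected & !(assoc$snv %in% kept)
  .stageLog("prune", seed, length(kept), " SNV(s) after pruning")

  assocPath <- file.path(cfg$outDir, "association.tsv")
  out <- assoc
  for (col in c("maf", "chisq", "p")) out[[col]] <- .fmtNum(out[[col]])
  utils::write.table(out, assocPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  if (length(kept) == 0L)
    stop("runPipeline[network]: no SNV survived the screen; cannot build networks")

  .stageLog("network", seed, "building stratum networks")
  d <- dosages(gqc$genotypes)[, kept, drop = FALSE]
  if (anyNA(d)) {
    # mean-impute residual missing dosages (post-QC call rate > 0.95)
    for (j in seq_len(ncol(d)))
      d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  }
  nets <- stratifiedNetworks(d, prep$matrix, response, stratum,
                             cfg$network)

  .stageLog("compare", seed, "delta centrality and edge diff")
  paths <- list(association = assocPath)
  paths$networkA <- writeNetworkGraphML(nets$netA,
                                        file.path(cfg$outDir,
                                                  "network_attempt.graphml"))
  paths$networkB <- writeNetworkGraphML(
    nets$netB, file.path(cfg$outDir, "network_noattempt.graphml"))
  paths$edgesA <- writeEdgeListTSV(nets$netA,
                                   file.path(cfg$outDir,
                                             "edges_attempt.tsv"))
  paths$edgesB <- writeEdgeListTSV(nets$netB,
                                   file.path(cfg$outDir,
                                             "edges_noattempt.tsv"))
  deltaPath <- file.path(cfg$outDir, "delta_centrality.tsv")
  dt <- nets$delta
  dtOut <- data.frame(feature = dt$feature, block = dt$block,
                      c_attempt = .fmtNum(dt$centralityA),
                      c_noattempt = .fmtNum(dt$centralityB),
                      delta = .fmtNum(dt$delta), rank = dt$rank,
                      stringsAsFactors = FALSE)
  utils::write.table(dtOut, deltaPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths$delta <- deltaPath
  for (nm in c("onlyA", "onlyB", "shared")) {
    pth <- file.path(cfg$outDir, paste0("edges_", nm, ".tsv"))
    d2 <- nets$diff[[nm]]
    for (col in intersect(names(d2),
                          c("weight", "p", "weightA", "weightB",
                            "weightChange")))
      d2[[col]] <- .fmtNum(d2[[col]])
    utils::write.table(d2, pth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths[[paste0("edges_", nm)]] <- pth
  }
  summaryPath <- file.path(cfg$outDir, "summary.json")
  jsonlite::write_json(
    list(n_samples = length(shared),
         n_snvs_qc = ncol(dosages(gqc$genotypes)),
         n_metabolites = ncol(prep$matrix),
         candidates = candidates, kept_after_ld = kept,
         top_features = topFeatures(nets$delta, 6L),
         seed = seed),
    summaryPath, auto_unbox = TRUE, digits = NA)
  paths$summary <- summaryPath

  manifest <- list(
    seed = seed,
    artifacts = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifestPath <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  .stageLog("done", seed, "manifest written to ", manifestPath)
  invisible(manifest)
}
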