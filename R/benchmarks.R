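#' Planted-structure recovery benchmark
#'
#' Runs the full stratified analysis (preprocess, per-stratum network
#' build, delta centrality) on simulated cohorts from [benchmarkConfig()]
#' across several seeds and aggregates recovery of the planted group-
#' specific structure. Edge calls are made under Benjamini-Hochberg
#' FDR control by default: a benchmark scored on its false-discovery
#' proportion should call edges with multiplicity control, whereas the
#' [runPipeline()] default mirrors the nominal per-edge thresholds of the
#' analysis this package reproduces.
#'
#' @param seeds integer vector of simulation seeds.
#' @param topK delta-centrality top list size for hub scoring, default 3.
#' @param network network configuration; default
#'   \code{networkConfig(bhCorrect = TRUE)}.
#' @param null logical; run the null variant (no planted structure) and
#'   score the designated hub SNV's top-K rate only.
#' @return list: \code{sensitivity} (pooled over planted edges),
#'   \code{fdp} (pooled false-discovery proportion of group-specific edge
#'   calls), \code{hubTopKRate}, \code{perSeed} (data.frame).
#' @export
recoveryBenchmark <- function(seeds, topK = 3L,
                              network = networkConfig(bhCorrect = TRUE),
                              null = FALSE) {
  hubId <- "snv001"
  rows <- lapply(seeds, function(sd) {
    cfg <- benchmarkConfig(seed = sd, null = null)
    co <- generateCohort(cfg)
    prep <- preprocessMetabolites(co$metabolites)
    netCfg <- network
    netCfg$seed <- as.integer(sd)
    nets <- stratifiedNetworks(dosages(co$genotypes), prep$matrix,
                               co$phenotypes$response,
                               co$phenotypes$attempt, netCfg)
    if (null) {
      dt <- nets$delta
      m <- match(hubId, dt$feature)
      hubTop <- !is.na(m) && dt$rank[m] <= topK && dt$delta[m] > 0
      return(data.frame(seed = sd, nRecovered = NA_integer_,
                        nPlanted = 0L, nFalseCalls = NA_integer_,
                        nCalls = NA_integer_, hubTopK = hubTop))
    }
    sc <- scoreRecovery(nets$delta, nets$netA, nets$netB, co$truth,
                        topK = topK)
    hub <- sc$featureRanks[sc$featureRanks$feature == hubId, ]
    data.frame(seed = sd, nRecovered = sum(sc$recovered),
               nPlanted = length(sc$recovered),
               nFalseCalls = round(sc$fdp * sc$nCalls),
               nCalls = sc$nCalls,
               hubTopK = isTRUE(hub$inTopK[1]))
  })
  perSeed <- do.call(rbind, rows)
  list(
    sensitivity = if (null) NA_real_ else
      sum(perSeed$nRecovered) / sum(perSeed$nPlanted),
    fdp = if (null) NA_real_ else {
      tot <- sum(perSeed$nCalls)
      if (tot == 0) 0 else sum(perSeed$nFalseCalls) / tot
    },
    hubTopKRate = mean(perSeed$hubTopK),
    perSeed = perSeed)
}

#' Null calibration of the genotypic chi-square screen
#'
#' Simulates cohorts with no planted SNV-stratum association and measures
#' the fraction of SNVs reaching p <= alpha, pooled across seeds. Under the
#' null this fraction should sit near alpha.
#'
#' @param seeds integer vector of simulation seeds.
#' @param nSnvs SNVs per cohort, default 200.
#' @param nPerGroup stratum sizes, default the study-sized c(46, 302).
#' @param alpha screen level, default 0.05.
#' @return list: \code{rate} (pooled selection fraction), \code{nTests},
#'   \code{band} (the 99% binomial band around alpha for nTests draws).
#' @export
nullCalibration <- function(seeds, nSnvs = 200L,
                            nPerGroup = c(46L, 302L), alpha = 0.05) {
  hits <- vapply(seeds, function(sd) {
    cfg <- simConfig(
      nPerGroup = nPerGroup, nSnvs = as.integer(nSnvs),
      nMetabolites = 4L,
      classBlocks = data.frame(name = "other", size = 4L, rho = 0,
                               stringsAsFactors = FALSE),
      plantedEffects = data.frame(snv = integer(), metabolite = integer(),
                                  beta = numeric(), group = character(),
                                  stringsAsFactors = FALSE),
      responseModel = data.frame(metabolite = integer(), coef = numeric(),
                                 group = character(),
                                 stringsAsFactors = FALSE),
      missingRate = 0, seed = sd)
    co <- generateCohort(cfg)
    assoc <- snvAssociation(co$genotypes, co$phenotypes$attempt)
    sum(assoc$p <= alpha)
  }, numeric(1))
  nTests <- length(seeds) * nSnvs
  half <- stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / nTests)
  list(rate = sum(hits) / nTests, nTests = nTests,
       band = c(alpha - half, alpha + half))
}
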