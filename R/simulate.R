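.emptyEffects <- function()
  data.frame(snv = integer(), metabolite = integer(), beta = numeric(),
             group = character(), stringsAsFactors = FALSE)

.emptyResponseModel <- function()
  data.frame(metabolite = integer(), coef = numeric(), group = character(),
             stringsAsFactors = FALSE)

#' Planted-effect slope for a target dosage-metabolite correlation
#'
#' For a metabolite generated as unit-variance noise plus beta * dosage with
#' dosage ~ Binomial(2, maf), the population correlation is
#' \code{r = beta * sd_g / sqrt(beta^2 var_g + 1)} with
#' \code{var_g = 2 maf (1 - maf)}. This inverts that relation.
#'
#' @param r target absolute correlation in (0, 1).
#' @param maf minor allele frequency of the SNV.
#' @return the slope beta (standardized units per allele copy).
#' @export
betaForCor <- function(r, maf) {
  stopifnot(r > 0, r < 1, maf > 0, maf <= 0.5)
  v <- 2 * maf * (1 - maf)
  sqrt(r^2 / (1 - r^2) / v)
}

#' Create a synthetic cohort configuration
#'
#' Defaults emulate the two-stratum pharmacogenomic study design this
#' package targets: 46 participants with and 302 without a lifetime history
#' of suicide attempt; candidate biallelic SNVs with MAF drawn from
#' [0.05, 0.5]; 153 metabolites in five correlated analyte-class blocks
#' (exchangeable within-block correlation 0.3); a handful of group-specific
#' SNV-to-metabolite effects sized to give |correlation| of about 0.4; a
#' binary treatment response linked to metabolites in the no-attempt
#' stratum only, with marginal response rate about two thirds; sparse
#' completely-at-random metabolite missingness.
#'
#' @param nPerGroup integer(2), samples in strata A ("attempt") and B
#'   ("no attempt"). Default c(46, 302).
#' @param nSnvs number of SNVs, default 20.
#' @param mafRange MAF range, default c(0.05, 0.5).
#' @param snvMaf optional fixed per-SNV MAF vector (length nSnvs).
#' @param assocSnvs optional data.frame (snv, mafA, mafB) planting
#'   stratum-specific MAF (a genotype-stratum association).
#' @param nMetabolites default 153.
#' @param classBlocks data.frame (name, size, rho); default: five p180-style
#'   analyte classes sized 28/21/19/70/15 with rho 0.3.
#' @param plantedEffects data.frame (snv, metabolite, beta, group); default:
#'   three group-specific effects mirroring the qualitative structure of
#'   stratum-specific SNV-metabolite correlation differences.
#' @param responseModel data.frame (metabolite, coef, group); default: two
#'   metabolites with log-odds coefficient 0.5 active in stratum B.
#' @param responseRate target marginal response rate, default 2/3.
#' @param duplicateSnvs optional data.frame (from, to) of perfect-LD copies.
#' @param missingRate MCAR metabolite missingness, default 0.002.
#' @param seed integer seed, default 1.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nPerGroup = c(46L, 302L),
                      nSnvs = 20L,
                      mafRange = c(0.05, 0.5),
                      snvMaf = numeric(),
                      assocSnvs = NULL,
                      nMetabolites = 153L,
                      classBlocks = NULL,
                      plantedEffects = NULL,
                      responseModel = NULL,
                      responseRate = 2 / 3,
                      duplicateSnvs = NULL,
                      missingRate = 0.002,
                      seed = 1L) {
  if (is.null(classBlocks)) {
    if (nMetabolites == 153L) {
      classBlocks <- data.frame(
        name = c("acylcarnitine", "amino acid", "biogenic amine",
                 "glycerophospholipid", "sphingolipid"),
        size = c(28L, 21L, 19L, 70L, 15L), rho = 0.3,
        stringsAsFactors = FALSE)
    } else {
      classBlocks <- data.frame(name = "other", size = as.integer(nMetabolites),
                                rho = 0.3, stringsAsFactors = FALSE)
    }
  }
  if (is.null(plantedEffects)) {
    plantedEffects <- if (nSnvs >= 3L && nMetabolites >= 6L) {
      data.frame(snv = c(1L, 1L, 1L, 2L, 2L, 3L),
                 metabolite = c(1L, 2L, 3L, 4L, 5L, 6L),
                 beta = betaForCor(0.4, 0.3),
                 group = c("B", "B", "B", "B", "B", "A"),
                 stringsAsFactors = FALSE)
    } else .emptyEffects()
  }
  if (is.null(responseModel)) {
    responseModel <- if (nMetabolites >= 2L)
      data.frame(metabolite = c(1L, 2L), coef = 0.5, group = "B",
                 stringsAsFactors = FALSE)
    else .emptyResponseModel()
  }
  if (is.null(assocSnvs))
    assocSnvs <- data.frame(snv = integer(), mafA = numeric(),
                            mafB = numeric(), stringsAsFactors = FALSE)
  if (is.null(duplicateSnvs))
    duplicateSnvs <- data.frame(from = integer(), to = integer(),
                                stringsAsFactors = FALSE)
  new("SimConfig",
      nPerGroup = as.integer(nPerGroup), nSnvs = as.integer(nSnvs),
      mafRange = as.numeric(mafRange), snvMaf = as.numeric(snvMaf),
      assocSnvs = assocSnvs, nMetabolites = as.integer(nMetabolites),
      classBlocks = classBlocks, plantedEffects = plantedEffects,
      responseModel = responseModel, responseRate = responseRate,
      duplicateSnvs = duplicateSnvs, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Benchmark configuration with a planted differential hub
#'
#' The standard planted-structure benchmark: two equal strata of 400
#' samples, 10 SNVs, 40 metabolites in five blocks (rho = 0.3), four
#' SNV-to-metabolite effects planted on a single hub SNV in stratum A only,
#' sized for |correlation| of about 0.4, and a stratum-specific MAF
#' difference on the hub so the association screen retains it. Used by the
#' recovery benchmarks; the null variant drops all planted structure.
#'
#' @param seed integer seed.
#' @param null logical; TRUE removes every planted effect (null cohort).
#' @return A [SimConfig-class].
#' @export
benchmarkConfig <- function(seed = 1L, null = FALSE) {
  hubMafA <- 0.42
  hubMafB <- 0.25
  effects <- data.frame(
    snv = 1L, metabolite = c(1L, 9L, 17L, 25L),
    beta = betaForCor(0.4, hubMafA), group = "A",
    stringsAsFactors = FALSE)
  assoc <- data.frame(snv = 1L, mafA = hubMafA, mafB = hubMafB,
                      stringsAsFactors = FALSE)
  simConfig(
    nPerGroup = c(400L, 400L), nSnvs = 10L, nMetabolites = 40L,
    classBlocks = data.frame(
      name = c("acylcarnitine", "amino acid", "biogenic amine",
               "glycerophospholipid", "sphingolipid"),
      size = 8L, rho = 0.3, stringsAsFactors = FALSE),
    plantedEffects = if (null) .emptyEffects() else effects,
    assocSnvs = if (null) NULL else assoc,
    responseModel = .emptyResponseModel(),
    missingRate = 0.002, seed = seed)
}

.sampleGroups <- function(config) {
  nA <- config@nPerGroup[1]
  nB <- config@nPerGroup[2]
  n <- nA + nB
  ids <- sprintf("S%04d", seq_len(n))
  list(ids = ids, attempt = c(rep(TRUE, nA), rep(FALSE, nB)), n = n)
}

#' Generate a synthetic two-stratum multi-omics cohort
#'
#' Draws genotypes per SNV as alternate-allele counts ~ Binomial(2, MAF),
#' i.i.d. across samples (MAF stratum-specific for SNVs in
#' \code{assocSnvs}); metabolites from a block factor model, metabolite j in
#' block b being \code{sqrt(rho) z_b + sqrt(1 - rho) eps_j} with standard
#' normal factors (exchangeable within-block correlation rho, cross-block
#' independence), plus \code{beta * dosage} for every planted effect active
#' in the sample's group; a binary treatment response from a logistic model
#' over the configured metabolite links whose intercept is solved by 1-D
#' root finding to hit the target marginal response rate; and completely-at-
#' random metabolite missingness. Depression-severity totals (baseline and
#' week 8) are generated consistently with the drawn response flag so the
#' responder derivation reproduces it exactly. The same configuration
#' (including seed) yields bit-identical output.
#'
#' @param config A [SimConfig-class] from [simConfig()].
#' @return list: \code{genotypes} ([GenotypeMatrix-class]),
#'   \code{metabolites} ([MetaboliteMatrix-class]), \code{phenotypes}
#'   (data.frame: sample_id, attempt, baseline_qids, week8_qids, response,
#'   age, sex, onset_before_18), \code{truth} ([SimTruth-class]).
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  smp <- .sampleGroups(config)
  n <- smp$n
  attempt <- smp$attempt

  ## genotypes -------------------------------------------------------------
  p <- config@nSnvs
  maf <- if (length(config@snvMaf)) config@snvMaf else
    stats::runif(p, config@mafRange[1], config@mafRange[2])
  mafA <- maf
  mafB <- maf
  if (nrow(config@assocSnvs)) {
    mafA[config@assocSnvs$snv] <- config@assocSnvs$mafA
    mafB[config@assocSnvs$snv] <- config@assocSnvs$mafB
  }
  snvIds <- sprintf("snv%03d", seq_len(p))
  dosage <- matrix(NA_real_, n, p, dimnames = list(smp$ids, snvIds))
  for (j in seq_len(p)) {
    pr <- ifelse(attempt, mafA[j], mafB[j])
    dosage[, j] <- stats::rbinom(n, 2L, pr)
  }
  if (nrow(config@duplicateSnvs)) {
    for (r in seq_len(nrow(config@duplicateSnvs)))
      dosage[, config@duplicateSnvs$to[r]] <-
        dosage[, config@duplicateSnvs$from[r]]
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  info <- data.frame(
    snv = snvIds,
    chrom = as.character(rep_len(1:22, p)),
    pos = 1e6 * (seq_len(p) %/% 22 + 1) + seq_len(p),
    ref = ref, alt = unname(alt),
    gene = sprintf("GENE%03d", seq_len(p)),
    quality = rep(0.99, p), stringsAsFactors = FALSE)
  genotypes <- genotypeMatrix(dosage, info)

  ## metabolites -----------------------------------------------------------
  m <- config@nMetabolites
  cb <- config@classBlocks
  metIds <- sprintf("met%03d", seq_len(m))
  classes <- rep(cb$name, cb$size)
  M <- matrix(NA_real_, n, m, dimnames = list(smp$ids, metIds))
  col <- 1L
  for (b in seq_len(nrow(cb))) {
    z <- stats::rnorm(n)
    rho <- cb$rho[b]
    for (jj in seq_len(cb$size[b])) {
      M[, col] <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      col <- col + 1L
    }
  }
  pe <- config@plantedEffects
  if (nrow(pe)) {
    for (r in seq_len(nrow(pe))) {
      active <- switch(pe$group[r], A = attempt, B = !attempt,
                       both = rep(TRUE, n))
      M[active, pe$metabolite[r]] <- M[active, pe$metabolite[r]] +
        pe$beta[r] * dosage[active, pe$snv[r]]
    }
  }

  ## response --------------------------------------------------------------
  rm_ <- config@responseModel
  eta0 <- rep(0, n)
  if (nrow(rm_)) {
    for (r in seq_len(nrow(rm_))) {
      active <- switch(rm_$group[r], A = attempt, B = !attempt,
                       both = rep(TRUE, n))
      eta0[active] <- eta0[active] +
        rm_$coef[r] * M[active, rm_$metabolite[r]]
    }
  }
  target <- config@responseRate
  intercept <- stats::uniroot(
    function(b0) mean(stats::plogis(b0 + eta0)) - target,
    interval = c(-20, 20), tol = 1e-10)$root
  response <- stats::rbinom(n, 1L, stats::plogis(intercept + eta0)) == 1L

  ## severity totals consistent with the response flag ---------------------
  baseMean <- ifelse(attempt, 16.5, 14.9)
  baseline <- pmin(27L, pmax(6L, as.integer(round(
    stats::rnorm(n, baseMean, 3.3)))))
  redResp <- stats::runif(n, 0.5, 0.95)
  redNon <- stats::runif(n, 0.05, 0.45)
  week8 <- ifelse(response,
                  floor(baseline * (1 - redResp)),
                  pmin(baseline, ceiling(baseline * (1 - redNon))))
  week8 <- as.integer(pmin(27L, pmax(0L, week8)))

  ## covariates ------------------------------------------------------------
  age <- round(stats::rnorm(n, ifelse(attempt, 37.9, 42.0), 13), 1)
  sex <- ifelse(stats::runif(n) < ifelse(attempt, 0.74, 0.65), "F", "M")
  onset <- stats::runif(n) < ifelse(attempt, 0.65, 0.37)

  ## missingness (MCAR) ----------------------------------------------------
  if (config@missingRate > 0) {
    mask <- matrix(stats::runif(n * m) < config@missingRate, n, m)
    M[mask] <- NA_real_
  }

  phenotypes <- data.frame(
    sample_id = smp$ids, attempt = attempt,
    baseline_qids = baseline, week8_qids = week8,
    response = response, age = age, sex = sex,
    onset_before_18 = onset, stringsAsFactors = FALSE)

  effects <- pe
  if (nrow(effects)) {
    effects$snvId <- snvIds[effects$snv]
    effects$metaboliteId <- metIds[effects$metabolite]
  } else {
    effects$snvId <- character()
    effects$metaboliteId <- character()
  }
  links <- rm_
  if (nrow(links)) {
    links$metaboliteId <- metIds[links$metabolite]
    links$intercept <- intercept
  } else {
    links$metaboliteId <- character()
    links$intercept <- numeric()
  }
  truth <- new("SimTruth", effects = effects,
               maf = data.frame(snv = snvIds, mafA = mafA, mafB = mafB,
                                stringsAsFactors = FALSE),
               responseLinks = links, seed = config@seed)
  list(genotypes = genotypes,
       metabolites = metaboliteMatrix(M, classes),
       phenotypes = phenotypes, truth = truth)
}

#' Score recovery of planted group-specific structure
#'
#' Scores a stratified network analysis against the simulation truth. A
#' planted group-specific SNV-metabolite edge counts as recovered when it
#' is present in the planted group's network and either absent from the
#' other network or at least 50% weaker there (|s_other| <= 0.5 |s_group|).
#' A "group-specific edge call" is any SNV-metabolite edge satisfying the
#' same present-here, absent-or-halved-there rule in either direction; the
#' false-discovery proportion is the fraction of such calls that were not
#' planted. Delta-centrality ranks are reported for every planted SNV and
#' metabolite; a feature only counts as ranked when its delta is strictly
#' positive (a zero delta carries no differential signal, whatever the
#' tie-break order says).
#'
#' @param deltaTable data.frame from [deltaCentrality()].
#' @param netA,netB the stratum networks (A = planted group "A").
#' @param truth A [SimTruth-class] with at least one planted effect.
#' @param topK size of the top list used for \code{inTopK}, default 3.
#' @return list: \code{sensitivity}, \code{fdp}, \code{nCalls},
#'   \code{recovered} (logical per planted group-specific edge),
#'   \code{featureRanks} (data.frame feature, delta, rank, inTopK).
#' @export
scoreRecovery <- function(deltaTable, netA, netB, truth, topK = 3L) {
  stopifnot(is(truth, "SimTruth"))
  eff <- truthEffects(truth)
  if (nrow(eff) == 0L) stop("scoreRecovery: nothing to score")
  grpEff <- eff[eff$group %in% c("A", "B"), , drop = FALSE]

  eA <- netEdges(netA)
  eB <- netEdges(netB)
  kA <- .edgeKey(eA$from, eA$to)
  kB <- .edgeKey(eB$from, eB$to)
  wA <- setNames(abs(eA$weight), kA)
  wB <- setNames(abs(eB$weight), kB)
  specific <- function(key, here, there) {
    w1 <- here[key]
    w2 <- there[key]
    !is.na(w1) & (is.na(w2) | w2 <= 0.5 * w1)
  }
  recovered <- logical(nrow(grpEff))
  if (nrow(grpEff)) {
    keys <- .edgeKey(grpEff$snvId, grpEff$metaboliteId)
    inA <- specific(keys, wA, wB)
    inB <- specific(keys, wB, wA)
    recovered <- ifelse(grpEff$group == "A", inA, inB)
  }
  sensitivity <- if (nrow(grpEff)) mean(recovered) else NA_real_

  blockOf <- rbind(netNodes(netA)[c("feature", "block")],
                   netNodes(netB)[c("feature", "block")])
  blockOf <- blockOf[!duplicated(blockOf$feature), , drop = FALSE]
  isSnvMet <- function(e) {
    bf <- blockOf$block[match(e$from, blockOf$feature)]
    bt <- blockOf$block[match(e$to, blockOf$feature)]
    (bf == "snv" & bt == "metabolite") | (bf == "metabolite" & bt == "snv")
  }
  callsA <- if (nrow(eA)) kA[isSnvMet(eA) & specific(kA, wA, wB)] else
    character()
  callsB <- if (nrow(eB)) kB[isSnvMet(eB) & specific(kB, wB, wA)] else
    character()
  calls <- c(callsA, callsB)
  plantedKeys <- if (nrow(grpEff))
    .edgeKey(grpEff$snvId, grpEff$metaboliteId) else character()
  nCalls <- length(calls)
  fdp <- if (nCalls) mean(!(calls %in% plantedKeys)) else 0

  plantedFeats <- unique(c(eff$snvId, eff$metaboliteId))
  m <- match(plantedFeats, deltaTable$feature)
  featureRanks <- data.frame(
    feature = plantedFeats,
    delta = deltaTable$delta[m],
    rank = deltaTable$rank[m],
    stringsAsFactors = FALSE)
  featureRanks$inTopK <- !is.na(featureRanks$rank) &
    featureRanks$rank <= topK & featureRanks$delta > 0
  list(sensitivity = sensitivity, fdp = fdp, nCalls = nCalls,
       recovered = recovered, featureRanks = featureRanks)
}
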