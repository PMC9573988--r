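test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- simConfig(nPerGroup = c(20L, 40L), nSnvs = 6L, nMetabolites = 8L,
                   classBlocks = data.frame(name = "other", size = 8L,
                                            rho = 0.3),
                   seed = 11L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(abundances(a$metabolites), abundances(b$metabolites))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(truthEffects(a$truth), truthEffects(b$truth))
  # different seed changes the data
  cfg@seed <- 12L
  expect_false(identical(dosages(generateCohort(cfg)$genotypes),
                         dosages(a$genotypes)))
})

test_that("zero missing rate leaves the missingness mask all-false", {
  cfg <- nullSimConfig(c(15L, 15L), 4L, 6L, seed = 2L)
  co <- generateCohort(cfg)
  expect_false(any(missingnessMask(co$metabolites)))
})

test_that("invalid configurations name the offending field", {
  expect_error(simConfig(mafRange = c(0, 0.6)), "mafRange")
  expect_error(simConfig(missingRate = 0.7), "missingRate")
  expect_error(simConfig(nSnvs = 3, nMetabolites = 10,
                         classBlocks = data.frame(name = "x", size = 4L,
                                                  rho = 0.3)),
               "sum to nMetabolites")
  expect_error(
    simConfig(nSnvs = 2L, nMetabolites = 4L,
              classBlocks = data.frame(name = "x", size = 4L, rho = 0.3),
              plantedEffects = data.frame(snv = 5L, metabolite = 1L,
                                          beta = 1, group = "A")),
    "snv index")
})

test_that("empirical MAF concentrates at the configured value", {
  cfg <- simConfig(nPerGroup = c(5000L, 5000L), nSnvs = 3L,
                   snvMaf = c(0.3, 0.3, 0.3), nMetabolites = 2L,
                   classBlocks = data.frame(name = "x", size = 2L, rho = 0),
                   plantedEffects = data.frame(snv = integer(),
                                               metabolite = integer(),
                                               beta = numeric(),
                                               group = character()),
                   responseModel = data.frame(metabolite = integer(),
                                              coef = numeric(),
                                              group = character()),
                   missingRate = 0, seed = 6L)
  co <- generateCohort(cfg)
  phat <- colMeans(dosages(co$genotypes)) / 2
  bound <- 3 * sqrt(0.3 * 0.7 / (2 * 10000))
  expect_true(all(abs(phat - 0.3) < bound))
})

test_that("planted effects produce the closed-form dosage-metabolite correlation", {
  beta <- 0.5; maf <- 0.3
  cfg <- simConfig(nPerGroup = c(2500L, 2500L), nSnvs = 2L,
                   snvMaf = c(maf, maf), nMetabolites = 4L,
                   classBlocks = data.frame(name = "x", size = 4L, rho = 0),
                   plantedEffects = data.frame(snv = 1L, metabolite = 1L,
                                               beta = beta, group = "both"),
                   responseModel = data.frame(metabolite = integer(),
                                              coef = numeric(),
                                              group = character()),
                   missingRate = 0, seed = 3L)
  co <- generateCohort(cfg)
  r <- cor(dosages(co$genotypes)[, 1], abundances(co$metabolites)[, 1])
  vg <- 2 * maf * (1 - maf)
  expect_lt(abs(r - beta * sqrt(vg) / sqrt(beta^2 * vg + 1)), 0.05)
  # betaForCor inverts the same relation
  expect_equal(betaForCor(beta * sqrt(vg) / sqrt(beta^2 * vg + 1), maf),
               beta, tolerance = 1e-10)
})

test_that("unplanted metabolites have standard marginal moments", {
  cfg <- simConfig(nPerGroup = c(600L, 600L), nSnvs = 2L, nMetabolites = 6L,
                   classBlocks = data.frame(name = "x", size = 6L,
                                            rho = 0.3),
                   plantedEffects = data.frame(snv = integer(),
                                               metabolite = integer(),
                                               beta = numeric(),
                                               group = character()),
                   responseModel = data.frame(metabolite = integer(),
                                              coef = numeric(),
                                              group = character()),
                   missingRate = 0, seed = 8L)
  M <- abundances(generateCohort(cfg)$metabolites)
  n <- nrow(M)
  expect_true(all(abs(colMeans(M)) < 4 / sqrt(n)))
  expect_true(all(abs(apply(M, 2, var) - 1) < 0.2))
  # within-block correlation near rho, as designed
  offDiag <- cor(M)[upper.tri(diag(6))]
  expect_lt(abs(mean(offDiag) - 0.3), 0.06)
})

test_that("marginal response rate hits the configured target", {
  co <- generateCohort(simConfig(nPerGroup = c(500L, 3000L), seed = 4L))
  expect_lt(abs(mean(co$phenotypes$response) - 2 / 3), 0.03)
  # severity totals reproduce the response flag exactly
  expect_identical(
    deriveResponse(co$phenotypes$baseline_qids, co$phenotypes$week8_qids),
    co$phenotypes$response)
})

test_that("null cohorts keep the chi-square screen calibrated", {
  cal <- nullCalibration(seeds = 1:2, nSnvs = 200L)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / cal$nTests)
  expect_gt(cal$rate, 0.05 - half)
  expect_lt(cal$rate, 0.05 + half)
})

test_that("recovery scoring applies the present-and-halved rule", {
  truth <- new("SimTruth",
               effects = data.frame(snv = 1L, metabolite = 1L, beta = 1,
                                    group = "A", snvId = "g1",
                                    metaboliteId = "m1",
                                    stringsAsFactors = FALSE),
               maf = data.frame(snv = "g1", mafA = 0.3, mafB = 0.3),
               responseLinks = data.frame(), seed = 1L)
  blocks <- setNames(rep(c("snv", "metabolite"), 2),
                     c("g1", "m1", "g2", "m2"))
  eA <- data.frame(from = "g1", to = "m1", weight = 0.6, p = 1e-6)
  netA <- makeNet(eA, block = blocks)
  netB <- makeNet(data.frame(from = "g2", to = "m2", weight = 0.4,
                             p = 1e-4), block = blocks)
  dt <- deltaCentrality(netA, netB)
  sc <- scoreRecovery(dt, netA, netB, truth, topK = 3)
  expect_equal(sc$sensitivity, 1)
  # identical networks: planted "group-specific" edges unrecovered
  scSame <- scoreRecovery(deltaCentrality(netA, netA), netA, netA, truth)
  expect_equal(scSame$sensitivity, 0)
  # three planted edges all present only in the correct group's network
  truth3 <- truth
  truth3@effects <- data.frame(
    snv = c(1L, 1L, 2L), metabolite = c(1L, 2L, 2L), beta = 1,
    group = c("A", "A", "B"),
    snvId = c("g1", "g1", "g2"), metaboliteId = c("m1", "m2", "m2"),
    stringsAsFactors = FALSE)
  eA3 <- data.frame(from = c("g1", "g1"), to = c("m1", "m2"),
                    weight = 0.5, p = 1e-5)
  eB3 <- data.frame(from = "g2", to = "m2", weight = 0.5, p = 1e-5)
  netA3 <- makeNet(eA3, block = blocks)
  netB3 <- makeNet(eB3, block = blocks)
  sc3 <- scoreRecovery(deltaCentrality(netA3, netB3), netA3, netB3, truth3)
  expect_equal(sc3$sensitivity, 1)
  expect_equal(sc3$fdp, 0)
  # empty truth is an error
  truth0 <- truth
  truth0@effects <- truth@effects[0, ]
  expect_error(scoreRecovery(dt, netA, netB, truth0), "nothing to score")
})

test_that("duplicated SNV pairs survive generation for prune testing", {
  cfg <- simConfig(nPerGroup = c(30L, 30L), nSnvs = 4L, nMetabolites = 2L,
                   classBlocks = data.frame(name = "x", size = 2L,
                                            rho = 0),
                   plantedEffects = data.frame(snv = integer(),
                                               metabolite = integer(),
                                               beta = numeric(),
                                               group = character()),
                   responseModel = data.frame(metabolite = integer(),
                                              coef = numeric(),
                                              group = character()),
                   duplicateSnvs = data.frame(from = 1L, to = 2L),
                   missingRate = 0, seed = 9L)
  d <- dosages(generateCohort(cfg)$genotypes)
  expect_identical(d[, 1], d[, 2])
})
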