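test_that("genotypic chi-square matches hand-computed counts and the df=2 tail", {
  d <- c(rep(0, 10), rep(1, 10), rep(1, 10), rep(2, 10))
  s <- rep(c(TRUE, FALSE), each = 20)
  r <- genotypicChisq(d, s)
  expect_equal(r$chisq, 20)
  expect_identical(r$df, 2L)
  expect_equal(r$p, exp(-10), tolerance = 1e-12)
  # identical distributions -> 0 statistic, p = 1
  r0 <- genotypicChisq(rep(c(0, 1, 2), 4), rep(c(TRUE, FALSE), 6))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)
  # all-zero genotype column dropped -> 2x2, df = 1
  r1 <- genotypicChisq(c(0, 0, 1, 1, 0, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(r1$df, 1L)
  # monomorphic -> warning, p = 1, df = 0
  expect_warning(rm1 <- genotypicChisq(rep(1, 10), rep(c(TRUE, FALSE), 5)),
                 "one genotype")
  expect_identical(rm1$df, 0L)
  expect_equal(rm1$p, 1)
  expect_error(genotypicChisq(c(0, 1, 2), c(TRUE, TRUE, TRUE)), "empty")
})

test_that("chi-square equals brute-force sum((O-E)^2/E) on random tables", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(30:80, 1)
    d <- sample(0:2, n, replace = TRUE, prob = runif(3) + 0.1)
    s <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(s)) < 2) next
    r <- suppressWarnings(genotypicChisq(d, s))
    O <- unclass(r$counts)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_lt(abs(r$chisq - sum((O - E)^2 / E)), 1e-10)
    if (r$df == 2L) expect_lt(abs(r$p - exp(-r$chisq / 2)), 1e-12)
  }
})

test_that("candidate selection is inclusive at alpha and sorted by p", {
  res <- data.frame(snv = c("a", "b", "c"), p = c(0.051, 0.05, 0.001))
  expect_identical(selectCandidates(res, 0.05), c("c", "b"))
  expect_identical(selectCandidates(res[0, ]), character())
  expect_identical(selectCandidates(data.frame(snv = "x", p = 1)), character())
})

test_that("LD pruning keeps the smaller-p variant of a perfect pair", {
  set.seed(9)
  base <- sample(0:2, 60, replace = TRUE)
  d <- cbind(a = base, b = base,
             c = sample(0:2, 60, replace = TRUE))
  rownames(d) <- sprintf("s%02d", 1:60)
  info <- data.frame(snv = c("a", "b", "c"), chrom = "1", pos = 1:3)
  g <- genotypeMatrix(d, info)
  res <- data.frame(snv = c("a", "b", "c"), p = c(0.01, 0.2, 0.5))
  expect_identical(sort(ldPrune(g, res)), c("a", "c"))
  # uncorrelated variants are all kept
  d2 <- cbind(x = c(0, 0, 1, 1, 2, 2), y = c(0, 1, 0, 2, 1, 2))
  rownames(d2) <- sprintf("s%d", 1:6)
  stopifnot(abs(cor(d2[, 1], d2[, 2])) < 0.999)
  g2 <- genotypeMatrix(d2, data.frame(snv = c("x", "y"), chrom = "1",
                                      pos = 1:2))
  expect_setequal(ldPrune(g2, data.frame(snv = c("x", "y"), p = c(0.1, 0.2))),
                  c("x", "y"))
})

test_that("greedy pruning follows p-order: B and C both conflict with kept A only", {
  # construct dosage columns with r2(A,B), r2(A,C) > 0.8 and r2(B,C) small
  set.seed(21)
  n <- 400
  a <- sample(0:2, n, replace = TRUE)
  flip <- function(v, k) { v[sample(n, k)] <- sample(0:2, k, TRUE); v }
  b <- flip(a, 20)
  c_ <- flip(a, 20)
  r2 <- cor(cbind(a, b, c_))^2
  stopifnot(r2["a", "b"] > 0.8, r2["a", "c_"] > 0.8)
  d <- cbind(A = a, B = b, C = c_)
  rownames(d) <- sprintf("s%03d", 1:n)
  g <- genotypeMatrix(d, data.frame(snv = c("A", "B", "C"), chrom = "1",
                                    pos = 1:3))
  res <- data.frame(snv = c("A", "B", "C"), p = c(0.001, 0.01, 0.02))
  kept <- ldPrune(g, res)
  expect_identical(kept[1], "A")
  expect_false("B" %in% kept)
  if (r2["b", "c_"] <= 0.8) expect_false("C" %in% kept || r2["a", "c_"] <= 0.8)
})

test_that("pruning output is independent of input column order", {
  set.seed(14)
  n <- 120
  d <- sapply(1:6, function(i) sample(0:2, n, TRUE))
  d[, 2] <- d[, 1]
  d[, 5] <- ifelse(runif(n) < 0.9, d[, 4], sample(0:2, n, TRUE))
  colnames(d) <- sprintf("v%d", 1:6)
  rownames(d) <- sprintf("s%03d", 1:n)
  info <- data.frame(snv = colnames(d), chrom = rep(c("1", "2"), each = 3),
                     pos = 1:6)
  res <- data.frame(snv = colnames(d), p = c(0.5, 0.01, 0.3, 0.02, 0.2, 0.04))
  g1 <- genotypeMatrix(d, info)
  perm <- c(4, 1, 6, 2, 5, 3)
  g2 <- genotypeMatrix(d[, perm], info[perm, ])
  expect_setequal(ldPrune(g1, res), ldPrune(g2, res))
})

test_that("cohort comparison dispatches the demographics-table tests", {
  # Fisher on [[3,0],[0,3]]: full hypergeometric enumeration gives 2/C(6,3)
  vals <- c(rep("yes", 3), rep("no", 3))
  strat <- rep(c(TRUE, FALSE), each = 3)
  f <- cohortCompare(vals, "categorical", strat)
  expect_equal(f$p.value, 2 / choose(6, 3), tolerance = 1e-12)
  # identical strata, continuous -> t = 0, p = 1
  v2 <- rep(c(1.2, 3.4, 5.6), 2)
  t2 <- cohortCompare(v2, "continuous", strat)
  expect_equal(unname(t2$statistic), 0)
  expect_equal(t2$p.value, 1)
  # ordinal uses Kruskal-Wallis with ties
  v3 <- c(1, 1, 2, 2, 3, 3)
  k3 <- cohortCompare(v3, "ordinal", strat)
  kw <- stats::kruskal.test(v3, factor(strat))
  expect_equal(k3$p.value, kw$p.value)
  expect_warning(cohortCompare(rep(1, 6), "continuous", strat), "degenerate")
})

test_that("Fisher p on any 2x2 equals the hypergeometric enumeration oracle", {
  set.seed(55)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    ft <- stats::fisher.test(tab)$p.value
    # oracle: enumerate all tables with the observed margins
    rs <- rowSums(tab); cs <- colSums(tab)
    a <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    pr <- dhyper(a, rs[1], rs[2], cs[1])
    pObs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
    oracle <- sum(pr[pr <= pObs * (1 + 1e-7)])
    got <- cohortCompare(
      rep(rep(c("x", "y"), 2), c(t(tab))),
      "categorical",
      rep(c(TRUE, FALSE), rowSums(tab)))$p.value
    expect_equal(got, ft, tolerance = 1e-12)
    expect_equal(got, oracle, tolerance = 1e-7)
  }
})

test_that("early-onset depression counts give a p-value of the printed order", {
  # 30/46 vs 112/302 early-onset, reconstructed from the cohort table
  onset <- c(rep(TRUE, 30), rep(FALSE, 16), rep(TRUE, 112), rep(FALSE, 190))
  strat <- rep(c(TRUE, FALSE), c(46, 302))
  p <- cohortCompare(onset, "categorical", strat)$p.value
  expect_gt(p, 6e-5)
  expect_lt(p, 6e-3)
})
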