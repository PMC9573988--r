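test_that("single-column fits reproduce the trivial geometry", {
  set.seed(1)
  x <- omicsBlock(matrix(rnorm(20), 20, 1,
                         dimnames = list(sprintf("s%02d", 1:20), "x1")))
  fit <- plsFit(x, x, ncomp = 1)
  expect_equal(abs(cor(x[, 1], plsScores(fit)[, 1])), 1, tolerance = 1e-10)
  expect_equal(similarityMatrix(fit, x, x)[1, 1], 1, tolerance = 1e-10)
  # exactly orthogonal mean-zero X columns, Y = first column
  q <- cbind(a = c(rep(c(1, -1), 5), rep(0, 10)),
             b = c(rep(0, 10), rep(c(1, -1), 5)))
  X2 <- omicsBlock(matrix(q, 20, 2, dimnames = list(rownames(x),
                                                    c("a", "b"))))
  Y2 <- X2[, 1, drop = FALSE]
  f2 <- plsFit(X2, Y2, ncomp = 1)
  expect_equal(unname(abs(f2@xWeights["a", 1])), 1, tolerance = 1e-8)
  expect_lt(abs(f2@xWeights["b", 1]), 1e-8)
})

test_that("full-rank similarity equals the Pearson cross-correlation", {
  set.seed(2024)
  for (i in 1:50) {
    n <- 20
    px <- sample(2:6, 1); py <- sample(2:6, 1)
    X <- randomBlock(n, px, "x")
    Y <- randomBlock(n, py, "y")
    fit <- suppressWarnings(plsFit(X, Y, ncomp = px))
    s <- similarityMatrix(fit, X, Y)
    expect_lt(max(abs(s - cor(X, Y))), 1e-6)
  }
})

test_that("scores stay orthogonal and |s| <= 1 under sparsity", {
  set.seed(303)
  for (i in 1:25) {
    n <- sample(15:40, 1)
    X <- randomBlock(n, sample(3:8, 1), "x")
    Y <- randomBlock(n, sample(3:8, 1), "y")
    kx <- sample(1:ncol(X), 1); ky <- sample(1:ncol(Y), 1)
    H <- min(3, ncol(X))
    fit <- suppressWarnings(plsFit(X, Y, ncomp = H, keepX = kx, keepY = ky))
    G <- crossprod(plsScores(fit))
    if (fit@ncomp > 1)
      expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
    expect_lte(max(abs(similarityMatrix(fit, X, Y))), 1 + 1e-10)
  }
})

test_that("edge significance follows the correlation t-test", {
  expect_equal(edgeSignificance(0, 50), 1)
  expect_equal(edgeSignificance(1, 50), 0)
  expect_equal(edgeSignificance(-1, 50), 0)
  # oracle: t CDF directly
  s <- 0.1; n <- 348
  tval <- s * sqrt((n - 2) / (1 - s^2))
  expect_equal(edgeSignificance(s, n), 2 * pt(tval, n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(edgeSignificance(0.1, 348), 0.0624, tolerance = 1e-3)
  expect_error(edgeSignificance(0.5, 2), "3 samples")
})

test_that("network thresholds are strict on both |s| and p", {
  # deterministic construction with sample correlation exactly r:
  # x and e have disjoint support, equal norms, zero means
  n <- 400
  x <- c(rep(1, 100), rep(-1, 100), rep(0, 200))
  e <- c(rep(0, 200), rep(1, 100), rep(-1, 100))
  mk <- function(r) {
    y <- r * x + sqrt(1 - r^2) * e
    blocks <- list(
      snv = matrix(x, ncol = 1, dimnames = list(sprintf("s%03d", 1:n), "g1")),
      metabolite = matrix(y, ncol = 1,
                          dimnames = list(sprintf("s%03d", 1:n), "m1")))
    buildNetwork(blocks, networkConfig())
  }
  netAt <- mk(0.10)
  expect_identical(nrow(netEdges(netAt)), 0L)    # |s| = 0.10 not > 0.10
  netAbove <- mk(0.11)
  expect_identical(nrow(netEdges(netAbove)), 1L)
  expect_equal(netEdges(netAbove)$weight, 0.11, tolerance = 1e-9)
})

test_that("a planted strong pair yields exactly one edge and an empty null network", {
  set.seed(88)
  n <- 100
  g <- rnorm(n)
  y <- 0.9 * g + sqrt(1 - 0.81) * rnorm(n)
  ids <- sprintf("s%03d", 1:n)
  net <- buildNetwork(list(
    snv = matrix(g, ncol = 1, dimnames = list(ids, "g1")),
    metabolite = matrix(y, ncol = 1, dimnames = list(ids, "m1"))))
  expect_identical(nrow(netEdges(net)), 1L)
  expect_identical(sort(netNodes(net)$feature), c("g1", "m1"))
  # all similarities below threshold -> empty network
  x2 <- c(rep(1, 50), rep(-1, 50))
  y2 <- rep(c(1, -1), 50)   # exactly orthogonal to x2
  net0 <- buildNetwork(list(
    snv = matrix(x2, ncol = 1, dimnames = list(ids, "g1")),
    metabolite = matrix(y2, ncol = 1, dimnames = list(ids, "m1"))))
  expect_identical(nrow(netNodes(net0)), 0L)
  expect_identical(nrow(netEdges(net0)), 0L)
})

test_that("edge set is invariant to feature and sample input order", {
  set.seed(17)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, sprintf("g%d", 1:4)))
  Y <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, sprintf("m%d", 1:5)))
  Y[, 2] <- 0.6 * X[, 3] + 0.8 * Y[, 2]
  cfg <- networkConfig(ncomp = 2)
  key <- function(net) {
    e <- netEdges(net)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  n1 <- buildNetwork(list(snv = X, metabolite = Y), cfg)
  n2 <- buildNetwork(list(snv = X[, c(3, 1, 4, 2)],
                          metabolite = Y[, 5:1]), cfg)
  perm <- sample(n)
  n3 <- buildNetwork(list(snv = X[perm, ], metabolite = Y[perm, ]), cfg)
  expect_identical(key(n1), key(n2))
  expect_identical(key(n1), key(n3))
})

test_that("Louvain labels match the exhaustive modularity maximizer on two cliques", {
  e <- data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                  to = c("b", "c", "c", "e", "f", "f", "d"),
                  weight = c(1, 1, 1, 1, 1, 1, 0.25), p = 0)
  net <- makeNet(e)
  labels <- setNames(netNodes(net)$community, netNodes(net)$feature)
  ids <- c("a", "b", "c", "d", "e", "f")
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  A[cbind(e$from, e$to)] <- e$weight
  A[cbind(e$to, e$from)] <- e$weight
  best <- NULL; bestQ <- -Inf
  for (p in allPartitions(6)) {
    lab <- integer(6)
    for (k in seq_along(p)) lab[p[[k]]] <- k
    q <- bruteModularity(A, lab)
    if (q > bestQ) { bestQ <- q; best <- lab }
  }
  # oracle finds the two cliques; detected labels must induce it
  expect_identical(unname(labels[ids] == labels["a"]), best == best[1])
  expect_equal(networkModularity(net), bestQ, tolerance = 1e-12)
  # single clique -> one community
  e1 <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                   weight = 1, p = 0)
  expect_identical(unique(netNodes(makeNet(e1))$community), 0L)
})

test_that("achieved modularity is at least the one-community baseline", {
  set.seed(41)
  for (i in 1:10) {
    nn <- sample(5:12, 1)
    ids <- sprintf("n%02d", 1:nn)
    e <- data.frame(from = sample(ids, 2 * nn, TRUE),
                    to = sample(ids, 2 * nn, TRUE),
                    weight = runif(2 * nn, 0.2, 1), p = 0)
    e <- e[e$from != e$to, ]
    e <- e[!duplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))), ]
    if (!nrow(e)) next
    net <- makeNet(e)
    nd <- netNodes(net)
    trivial <- setNames(rep(0L, nrow(nd)), nd$feature)
    expect_gte(networkModularity(net),
               networkModularity(net, trivial) - 1e-12)
  }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  # closed form on the 3-node path
  e <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1, p = 0)
  cen <- eigenCentrality(makeNet(e))
  expect_equal(unname(cen[c("a", "b", "c")]), c(1 / sqrt(2), 1, 1 / sqrt(2)),
               tolerance = 1e-8)
  # complete graph: all 1 by symmetry
  e2 <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                   weight = 1, p = 0)
  expect_equal(max(abs(eigenCentrality(makeNet(e2)) - 1)), 0,
               tolerance = 1e-9)
  # random weighted graphs vs eigen()
  set.seed(202)
  for (i in 1:40) {
    nn <- sample(4:50, 1)
    ids <- sprintf("n%02d", 1:nn)
    e <- data.frame(from = sample(ids, 2 * nn, TRUE),
                    to = sample(ids, 2 * nn, TRUE),
                    weight = runif(2 * nn, -1, 1), p = 0)
    e <- e[e$from != e$to, ]
    e <- e[!duplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))), ]
    if (!nrow(e)) next
    net <- makeNet(e)
    used <- netNodes(net)$feature
    cen <- eigenCentrality(net)
    A <- matrix(0, length(used), length(used), dimnames = list(used, used))
    w <- abs(e$weight)
    A[cbind(e$from, e$to)] <- w
    A[cbind(e$to, e$from)] <- w
    v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
    v <- v / max(v)
    expect_lt(max(abs(cen[used] - v)), 1e-8)
    expect_equal(max(cen), 1)
    expect_gte(min(cen), 0)
  }
})

test_that("the NIPALS fit agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(909)
  X <- randomBlock(25, 4, "x")
  Y <- randomBlock(25, 3, "y")
  mine <- plsFit(X, Y, ncomp = 3)
  ref <- mixOmics::pls(X, Y, ncomp = 3, mode = "regression", scale = FALSE)
  for (h in 1:3)
    expect_gt(abs(cor(plsScores(mine)[, h], ref$variates$X[, h])),
              1 - 1e-8)
  # sparse variant: same support on a clear planted signal (hard top-k vs
  # soft thresholding differ in coefficients, not in selection)
  Y2 <- Y
  Y2[, 1] <- omicsBlock(matrix(0.8 * X[, 2] + 0.4 * Y[, 1], ncol = 1,
                               dimnames = list(rownames(Y), "y1")))
  sp <- plsFit(X, Y2, ncomp = 1, keepX = 2)
  refSp <- mixOmics::spls(X, Y2, ncomp = 1, keepX = 2,
                          mode = "regression", scale = FALSE)
  expect_identical(which(sp@xWeights[, 1] != 0),
                   which(refSp$loadings$X[, 1] != 0))
})
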