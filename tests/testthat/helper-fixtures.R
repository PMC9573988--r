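# Build an OmicsNetwork directly from an edge table (bypassing the PLS
# stage) so graph algorithms can be tested on hand-constructed graphs.
makeNet <- function(edges, block = NULL, n = 10L) {
  feats <- sort(union(edges$from, edges$to))
  if (is.null(block)) block <- setNames(rep("snv", length(feats)), feats)
  if (is.null(edges$p)) edges$p <- 0
  nodes <- data.frame(feature = feats, block = unname(block[feats]),
                      community = 0L, centrality = 1,
                      stringsAsFactors = FALSE)
  net <- new("OmicsNetwork", nodes = nodes, edges = edges,
             n = as.integer(n), config = list(rThreshold = 0.1,
                                              alpha = 0.05))
  cen <- eigenCentrality(net)
  net@nodes$centrality <- unname(cen[net@nodes$feature])
  net@nodes$community <- unname(detectCommunities(net, 1L)[net@nodes$feature])
  net
}

emptyNet <- function() {
  new("OmicsNetwork",
      nodes = data.frame(feature = character(), block = character(),
                         community = integer(), centrality = numeric(),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         weight = numeric(), p = numeric(),
                         stringsAsFactors = FALSE),
      n = 10L, config = list())
}

# Random standardized block with named features, for PLS property tests.
randomBlock <- function(n, p, prefix, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  omicsBlock(m)
}

# Small metabolite matrix with controlled missingness.
smallMetabolites <- function(values, ids = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- if (is.null(ids)) sprintf("m%02d", seq_len(ncol(m))) else ids
  metaboliteMatrix(m)
}

# All set partitions of 1..n (Bell-number enumeration, n small), used as
# the exhaustive oracle for modularity maximization.
allPartitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in allPartitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Modularity of a labelled partition on an adjacency matrix (abs weights).
bruteModularity <- function(A, labels) {
  m2 <- sum(A)            # 2m for symmetric A with both triangles filled
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(labels, labels, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# Null cohort configuration: no planted structure at all.
nullSimConfig <- function(nPerGroup, nSnvs, nMetabolites = 10L, seed = 1L) {
  simConfig(
    nPerGroup = nPerGroup, nSnvs = nSnvs, nMetabolites = nMetabolites,
    classBlocks = data.frame(name = "other", size = as.integer(nMetabolites),
                             rho = 0.3, stringsAsFactors = FALSE),
    plantedEffects = data.frame(snv = integer(), metabolite = integer(),
                                beta = numeric(), group = character(),
                                stringsAsFactors = FALSE),
    responseModel = data.frame(metabolite = integer(), coef = numeric(),
                               group = character(), stringsAsFactors = FALSE),
    missingRate = 0, seed = seed)
}
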