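#' Network construction configuration
#'
#' Collects the tunable parameters of [buildNetwork()]: the association
#' threshold |s| > rThreshold and significance threshold p < alpha (both
#' strict), the number of PLS components, optional per-component sparsity,
#' and the seed for community detection.
#'
#' @param rThreshold association-magnitude threshold, default 0.1.
#' @param alpha edge significance level, default 0.05.
#' @param ncomp PLS components per block pair, default 3.
#' @param keepX,keepY optional kept-variable counts per component (NULL =
#'   all variables).
#' @param bhCorrect logical; apply Benjamini-Hochberg correction to edge
#'   p-values per block pair before thresholding. Off by default (nominal
#'   p-values).
#' @param seed integer seed for community detection, default 1.
#' @return a named list of class-checked parameters.
#' @export
networkConfig <- function(rThreshold = 0.1, alpha = 0.05, ncomp = 3L,
                          keepX = NULL, keepY = NULL, bhCorrect = FALSE,
                          seed = 1L) {
  stopifnot(rThreshold >= 0, rThreshold < 1, alpha > 0, alpha < 1,
            ncomp >= 1)
  list(rThreshold = rThreshold, alpha = alpha, ncomp = as.integer(ncomp),
       keepX = keepX, keepY = keepY, bhCorrect = isTRUE(bhCorrect),
       seed = as.integer(seed))
}

#' Build a thresholded multi-block association network
#'
#' For every unordered pair of blocks, fits a PLS model ([plsFit()]),
#' reconstructs the component similarity matrix ([similarityMatrix()]) and
#' its p-values ([edgeSignificance()]), and creates an edge iff
#' \code{|s| > rThreshold} and \code{p < alpha} (both strict). Only features
#' with at least one retained edge enter the network; single-feature blocks
#' (e.g. a binary outcome, standardized like any feature) are handled
#' identically. Communities (weighted Louvain on absolute weights) and
#' max-normalized eigenvector centralities are computed on the assembled
#' graph.
#'
#' @param blocks named list of feature matrices (samples x features, same
#'   samples in the same order across blocks; feature names unique across
#'   blocks). Typical names: "snv", "metabolite", "outcome". Matrices are
#'   standardized internally via [omicsBlock()].
#' @param config list from [networkConfig()].
#' @return An [OmicsNetwork-class].
#' @export
buildNetwork <- function(blocks, config = networkConfig()) {
  stopifnot(is.list(blocks), length(blocks) >= 2L,
            !is.null(names(blocks)), all(nzchar(names(blocks))))
  n <- nrow(as.matrix(blocks[[1]]))
  if (any(vapply(blocks, function(b) nrow(as.matrix(b)), 0L) != n))
    stop("buildNetwork: all blocks must share the same samples")
  if (n < 3L) stop("buildNetwork: need at least 3 shared samples")
  std <- lapply(blocks, omicsBlock)
  feats <- unlist(lapply(std, colnames), use.names = FALSE)
  if (anyDuplicated(feats))
    stop("buildNetwork: feature ids must be unique across blocks")
  blockOf <- rep(names(std), vapply(std, ncol, 0L))
  names(blockOf) <- feats
  edges <- list()
  pairs <- utils::combn(length(std), 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    X <- std[[i]]; Y <- std[[j]]
    H <- min(config$ncomp, ncol(X), n - 1L)
    # exactly orthogonal blocks admit no component: no edges for the pair
    fit <- tryCatch(
      suppressWarnings(plsFit(X, Y, ncomp = H, keepX = config$keepX,
                              keepY = config$keepY)),
      error = function(e) {
        if (grepl("no component", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(fit)) next
    s <- similarityMatrix(fit, X, Y)
    p <- edgeSignificance(s, n)
    if (config$bhCorrect)
      p <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
    sel <- which(abs(s) > config$rThreshold & p < config$alpha,
                 arr.ind = TRUE)
    if (nrow(sel)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = rownames(s)[sel[, 1]], to = colnames(s)[sel[, 2]],
        weight = s[sel], p = p[sel], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               weight = numeric(), p = numeric(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodeIds <- feats[feats %in% c(edges$from, edges$to)]
  nodes <- data.frame(feature = nodeIds,
                      block = unname(blockOf[nodeIds]),
                      community = rep(NA_integer_, length(nodeIds)),
                      centrality = rep(NA_real_, length(nodeIds)),
                      stringsAsFactors = FALSE)
  if (nrow(nodes)) {
    nodes$community <- 0L
    nodes$centrality <- 1
  }
  net <- new("OmicsNetwork", nodes = nodes, edges = edges,
             n = as.integer(n), config = config)
  if (nrow(nodes)) {
    cen <- eigenCentrality(net)
    com <- detectCommunities(net, seed = config$seed)
    net@nodes$centrality <- unname(cen[net@nodes$feature])
    net@nodes$community <- unname(com[net@nodes$feature])
  }
  methods::validObject(net)
  net
}

#' Convert an OmicsNetwork to an igraph graph
#'
#' @param net An [OmicsNetwork-class].
#' @param absWeights logical; use absolute edge weights (required by the
#'   community and centrality algorithms). Default TRUE.
#' @return an undirected igraph object with node attributes block,
#'   community, centrality and edge attributes weight, signedWeight, p.
#' @export
asIgraph <- function(net, absWeights = TRUE) {
  stopifnot(is(net, "OmicsNetwork"))
  e <- netEdges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to,
               weight = if (absWeights) abs(e$weight) else e$weight,
               signedWeight = e$weight, p = e$p,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = netNodes(net)$feature)
  nd <- netNodes(net)
  igraph::V(g)$block <- nd$block[match(igraph::V(g)$name, nd$feature)]
  igraph::V(g)$community <- nd$community[match(igraph::V(g)$name,
                                               nd$feature)]
  igraph::V(g)$centrality <- nd$centrality[match(igraph::V(g)$name,
                                                 nd$feature)]
  g
}

#' Louvain community detection on absolute edge weights
#'
#' Multilevel greedy modularity optimization (Louvain) on the absolute-
#' weight graph; modularity uses the standard weighted form
#' Q = (1/2m) sum_ij (w_ij - k_i k_j / 2m) delta(c_i, c_j). Deterministic
#' given the seed and node ordering. Labels are integers 0..C-1 ordered by
#' decreasing community size (ties by the smallest member feature id).
#'
#' @param net An [OmicsNetwork-class].
#' @param seed integer RNG seed.
#' @return named integer vector of community labels per feature; empty for
#'   an empty network.
#' @export
detectCommunities <- function(net, seed = 1L) {
  stopifnot(is(net, "OmicsNetwork"))
  if (nrow(netNodes(net)) == 0L) return(setNames(integer(), character()))
  g <- asIgraph(net, absWeights = TRUE)
  cl <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  mem <- igraph::membership(cl)
  sizes <- table(mem)
  firstMember <- vapply(names(sizes), function(cm)
    min(names(mem)[mem == as.integer(cm)]), character(1))
  ord <- names(sizes)[order(-as.integer(sizes), firstMember)]
  relabel <- setNames(seq_along(ord) - 1L, ord)
  out <- relabel[as.character(mem)]
  names(out) <- names(mem)
  out
}

#' Weighted modularity of a labelled partition
#'
#' @param net An [OmicsNetwork-class].
#' @param labels named community labels (defaults to the stored ones).
#' @return modularity Q of the partition on absolute weights.
#' @export
networkModularity <- function(net, labels = NULL) {
  g <- asIgraph(net, absWeights = TRUE)
  if (is.null(labels)) {
    nd <- netNodes(net)
    labels <- setNames(nd$community, nd$feature)
  }
  igraph::modularity(g, labels[igraph::V(g)$name] + 1L,
                     weights = igraph::E(g)$weight)
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of the absolute-weight adjacency matrix
#' by power iteration (convergence tolerance 1e-10 on the normalized
#' vector), starting from a uniform positive vector so the Perron vector is
#' reached. Entries are nonnegative and the result is normalized so the
#' maximum is exactly 1. On disconnected graphs the global leading
#' eigenvector is returned: nodes off the dominant component approach 0.
#'
#' @param net An [OmicsNetwork-class].
#' @return named numeric vector of centralities in [0, 1]; empty for an
#'   empty network.
#' @export
eigenCentrality <- function(net) {
  stopifnot(is(net, "OmicsNetwork"))
  nd <- netNodes(net)
  if (nrow(nd) == 0L) return(setNames(numeric(), character()))
  e <- netEdges(net)
  ids <- nd$feature
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w <- abs(e$weight)
  A[cbind(e$from, e$to)] <- A[cbind(e$from, e$to)] + w
  A[cbind(e$to, e$from)] <- A[cbind(e$to, e$from)] + w
  v <- rep(1 / sqrt(length(ids)), length(ids))
  # iterate on A + I: same eigenvectors, but strictly dominant leading
  # eigenvalue even on bipartite graphs (whose +/- lambda pair would
  # otherwise make plain power iteration oscillate)
  for (it in seq_len(100000L)) {
    vn <- drop(A %*% v) + v
    nv <- sqrt(sum(vn^2))
    if (nv == 0) break
    vn <- vn / nv
    if (max(abs(vn - v)) < 1e-10) { v <- vn; break }
    v <- vn
  }
  v <- abs(v)
  v <- v / max(v)
  setNames(v, ids)
}
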