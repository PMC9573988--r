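#' Delta eigenvector centrality between two stratum networks
#'
#' For each feature in the union of the two node sets, computes
#' \code{delta = |c_A - c_B|}, where c is the max-normalized eigenvector
#' centrality in each network and a feature absent from a network (no
#' significant edges there) carries centrality 0. Because centralities lie
#' in [0, 1], delta centrality ranges from 0 to 1, with 1 indicating the
#' greatest difference between strata in the number and quality of network
#' connections. The table is sorted by descending delta, ties broken by
#' feature id.
#'
#' @param netA network of stratum A (e.g. lifetime history of suicide
#'   attempt).
#' @param netB network of stratum B (no history).
#' @return data.frame: feature, block, centralityA, centralityB, delta,
#'   rank.
#' @export
deltaCentrality <- function(netA, netB) {
  stopifnot(is(netA, "OmicsNetwork"), is(netB, "OmicsNetwork"))
  ndA <- netNodes(netA)
  ndB <- netNodes(netB)
  if (nrow(ndA) == 0L && nrow(ndB) == 0L) {
    warning("deltaCentrality: both networks are empty")
    return(data.frame(feature = character(), block = character(),
                      centralityA = numeric(), centralityB = numeric(),
                      delta = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  feats <- sort(union(ndA$feature, ndB$feature))
  cA <- setNames(ndA$centrality, ndA$feature)[feats]
  cB <- setNames(ndB$centrality, ndB$feature)[feats]
  cA[is.na(cA)] <- 0
  cB[is.na(cB)] <- 0
  blk <- setNames(ndA$block, ndA$feature)[feats]
  blk[is.na(blk)] <- setNames(ndB$block, ndB$feature)[feats][is.na(blk)]
  tab <- data.frame(feature = feats, block = unname(blk),
                    centralityA = unname(cA), centralityB = unname(cB),
                    delta = abs(unname(cA) - unname(cB)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$delta, tab$feature), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Top differential features by delta centrality
#'
#' @param table data.frame from [deltaCentrality()].
#' @param k number of features to return (default 6); the whole table when
#'   shorter.
#' @return character vector of feature ids.
#' @export
topFeatures <- function(table, k = 6L) {
  stopifnot(k >= 1L)
  utils::head(table$feature, k)
}

.edgeKey <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "\r")
}

#' Edge-level comparison of two networks
#'
#' Partitions the union of both networks' edges into edges only in A, only
#' in B, and shared edges (with the weight change s_A - s_B), plus
#' per-feature degrees in each network. Ordering is deterministic (by
#' endpoint ids).
#'
#' @param netA,netB [OmicsNetwork-class] objects built on the same feature
#'   universe.
#' @return list: \code{onlyA}, \code{onlyB} (edge data.frames),
#'   \code{shared} (from, to, weightA, weightB, weightChange),
#'   \code{degrees} (feature, degreeA, degreeB).
#' @export
edgeDiff <- function(netA, netB) {
  stopifnot(is(netA, "OmicsNetwork"), is(netB, "OmicsNetwork"))
  eA <- netEdges(netA)
  eB <- netEdges(netB)
  kA <- .edgeKey(eA$from, eA$to)
  kB <- .edgeKey(eB$from, eB$to)
  onlyA <- eA[!(kA %in% kB), , drop = FALSE]
  onlyB <- eB[!(kB %in% kA), , drop = FALSE]
  shA <- eA[kA %in% kB, , drop = FALSE]
  mB <- match(.edgeKey(shA$from, shA$to), kB)
  shared <- data.frame(from = shA$from, to = shA$to,
                       weightA = shA$weight, weightB = eB$weight[mB],
                       weightChange = shA$weight - eB$weight[mB],
                       stringsAsFactors = FALSE)
  srt <- function(d) {
    d <- d[order(d$from, d$to), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  feats <- sort(union(c(eA$from, eA$to), c(eB$from, eB$to)))
  degA <- table(factor(c(eA$from, eA$to), levels = feats))
  degB <- table(factor(c(eB$from, eB$to), levels = feats))
  list(onlyA = srt(onlyA), onlyB = srt(onlyB), shared = srt(shared),
       degrees = data.frame(feature = feats,
                            degreeA = as.integer(degA),
                            degreeB = as.integer(degB),
                            stringsAsFactors = FALSE))
}
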