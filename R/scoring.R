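# Edge and node confidence measures: additive evidence Class score
# (classes A-E with rendering widths), FSWeight topological edge
# reliability, and the binomial-proportion node significance p-value.

#' High-throughput publication test
#'
#' A publication is high-throughput (HT) when it describes more than 500
#' interactions; the boundary is strict (exactly 500 is not HT).
#' Publications with unknown interaction count are treated as HT, the
#' conservative choice: unknown-scale papers can never upgrade an edge to
#' the top class on their own.
#'
#' @param interaction_count Integer vector of per-publication interaction
#'   counts; `NA` for unknown.
#' @return Logical vector.
#' @export
#' @examples
#' is_high_throughput(c(500, 501, 0, NA))
is_high_throughput <- function(interaction_count) {
  ifelse(is.na(interaction_count), TRUE, interaction_count > 500)
}

#' Publication component of the Class score
#'
#' +4 when the interaction is described in more than one paper with at
#' least one not high-throughput, +3 when described in more than one paper
#' (all HT), +1 for exactly one paper, 0 when unpublished.
#'
#' @param pub_counts Integer vector of interaction counts, one entry per
#'   publication supporting the pair (possibly empty); `NA` = unknown.
#' @return Integer score in \{0, 1, 3, 4\}.
#' @export
publication_component <- function(pub_counts) {
  n <- length(pub_counts)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  if (any(!is_high_throughput(pub_counts))) 4L else 3L
}

.CLASS_WIDTHS <- c(A = 2.5, B = 2.0, C = 1.5, D = 1.0, E = 0.5, unclassified = 0.5)

#' Class score of an evidence profile
#'
#' The total is additive: +4 for experimental evidence (0 if predicted),
#' the publication component (see [publication_component()]), and +1 when
#' the two partners share a selected cellular component.  Totals map to
#' classes A (9), B (7-8), C (6), D (5), E (4); totals below 4 are
#' `unclassified` and removed by any Class-score filter.  One exception
#' mirrors the published rule for novel interactions: an experimental pair
#' described in no paper is assigned class E even when its partners share
#' a cellular component.
#'
#' @param experimental Logical; any experimental evidence for the pair.
#' @param pub_counts Integer vector of interaction counts of the
#'   supporting publications (length = number of distinct publications).
#' @param same_cc Logical; non-empty intersection of the partners'
#'   selected cellular-component sets.
#' @return List with `total` (integer), `label` (one of `"A"`..`"E"`,
#'   `"unclassified"`) and `width` (edge rendering width: A 2.5, B 2.0,
#'   C 1.5, D 1.0, E and unclassified 0.5).
#' @export
#' @examples
#' class_score(TRUE, c(10, 600), TRUE)   # class A, total 9
#' class_score(TRUE, integer(), TRUE)    # novel interaction: class E
class_score <- function(experimental, pub_counts = integer(), same_cc = FALSE) {
  total <- (if (isTRUE(experimental)) 4L else 0L) +
    publication_component(pub_counts) +
    (if (isTRUE(same_cc)) 1L else 0L)
  label <- if (isTRUE(experimental) && length(pub_counts) == 0L) {
    "E"
  } else if (total >= 9L) "A"
  else if (total >= 7L) "B"
  else if (total == 6L) "C"
  else if (total == 5L) "D"
  else if (total == 4L) "E"
  else "unclassified"
  list(total = total, label = label, width = unname(.CLASS_WIDTHS[[label]]))
}

#' Edge width associated with a class label
#' @param label Character vector of class labels.
#' @return Numeric vector of widths.
#' @export
class_width <- function(label) {
  unname(.CLASS_WIDTHS[label])
}

#' Rank of a class label (A highest)
#' @param label Character vector of class labels.
#' @return Integer vector; A = 5 ... E = 1, unclassified = 0.
#' @export
class_rank <- function(label) {
  unname(c(A = 5L, B = 4L, C = 3L, D = 2L, E = 1L, unclassified = 0L)[label])
}

# ---------------------------------------------------------------- FSWeight

#' Average closed-neighborhood size of a graph
#' @param adj Named list: node id -> character vector of neighbors (open
#'   neighborhood, no self).
#' @param include_self Use closed neighborhoods (default TRUE).
#' @return Mean neighborhood size over all nodes.
#' @export
fsw_navg <- function(adj, include_self = TRUE) {
  if (length(adj) == 0L) return(0)
  mean(vapply(adj, length, integer(1)) + as.integer(include_self))
}

#' Functional Similarity Weight of a node pair
#'
#' FSWeight estimates the reliability of an interaction from the overlap
#' of the two nodes' neighborhoods.  With closed neighborhoods `N_u`,
#' `N_v`, common count `c = |N_u n N_v|`, exclusive counts
#' `e_u = |N_u \\ N_v|`, `e_v = |N_v \\ N_u|` and pseudo-counts
#' `lambda_uv = max(0, n_avg - (e_u + c))` (symmetrically for `v`), the
#' score is
#' `FSW = (2c / (e_u + 2c + lambda_uv)) * (2c / (e_v + 2c + lambda_vu))`.
#' The pseudo-count penalizes nodes with fewer neighbors than the graph
#' average, so sparse neighborhoods cannot produce spuriously high scores.
#' The score is symmetric, lies in [0, 1], is 0 for disjoint neighborhoods
#' and 1 for identical closed neighborhoods at least as large as `n_avg`.
#'
#' @param u,v Node ids.
#' @param adj Named list adjacency (open neighborhoods).
#' @param n_avg Average neighborhood size; computed from `adj` when `NULL`.
#' @param include_self Closed neighborhoods (default TRUE).
#' @param lambda_mode `"chua_pseudocount"` (default) or `"none"` to drop
#'   the pseudo-count correction.
#' @return Numeric scalar in [0, 1].
#' @export
fsw_score <- function(u, v, adj, n_avg = NULL, include_self = TRUE,
                      lambda_mode = c("chua_pseudocount", "none")) {
  lambda_mode <- match.arg(lambda_mode)
  if (!u %in% names(adj)) stop("node not in graph: ", u)
  if (!v %in% names(adj)) stop("node not in graph: ", v)
  if (is.null(n_avg)) n_avg <- fsw_navg(adj, include_self)
  Nu <- adj[[u]]; Nv <- adj[[v]]
  if (include_self) { Nu <- union(Nu, u); Nv <- union(Nv, v) }
  cc <- length(intersect(Nu, Nv))
  if (cc == 0L) return(0)
  eu <- length(setdiff(Nu, Nv))
  ev <- length(setdiff(Nv, Nu))
  if (lambda_mode == "chua_pseudocount") {
    luv <- max(0, n_avg - (eu + cc))
    lvu <- max(0, n_avg - (ev + cc))
  } else {
    luv <- 0; lvu <- 0
  }
  (2 * cc / (eu + 2 * cc + luv)) * (2 * cc / (ev + 2 * cc + lvu))
}

#' FSWeight for every edge of an edge list
#'
#' @param edges Data frame with columns `id_a`, `id_b`.
#' @param nodes Character vector of all node ids (isolated nodes allowed).
#' @inheritParams fsw_score
#' @return Numeric vector of scores, one per edge row.
#' @export
fsw_edge_scores <- function(edges, nodes = NULL, include_self = TRUE,
                            lambda_mode = "chua_pseudocount") {
  if (is.null(nodes)) nodes <- unique(c(edges$id_a, edges$id_b))
  adj <- adjacency_list(edges, nodes)
  n_avg <- fsw_navg(adj, include_self)
  if (nrow(edges) == 0L) return(numeric())
  vapply(seq_len(nrow(edges)), function(i) {
    fsw_score(edges$id_a[[i]], edges$id_b[[i]], adj, n_avg,
              include_self = include_self, lambda_mode = lambda_mode)
  }, numeric(1))
}

#' Adjacency list of an undirected edge list
#'
#' Self-loops are dropped (neighbor semantics exclude self); parallel
#' edges collapse.
#'
#' @param edges Data frame with columns `id_a`, `id_b`.
#' @param nodes Node universe; defaults to ids seen in `edges`.
#' @return Named list: node id -> sorted character vector of neighbors.
#' @export
adjacency_list <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(edges$id_a, edges$id_b))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) adj[[nd]] <- character()
  keep <- edges$id_a != edges$id_b
  ea <- edges$id_a[keep]; eb <- edges$id_b[keep]
  for (i in seq_along(ea)) {
    adj[[ea[[i]]]] <- c(adj[[ea[[i]]]], eb[[i]])
    adj[[eb[[i]]]] <- c(adj[[eb[[i]]]], ea[[i]])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# ------------------------------------------------- node significance

#' Binomial-proportion node significance
#'
#' For each node a raw z-score compares its interaction share in the
#' subnetwork with its share in the organism-filtered store:
#' `z = (k/n - K/N) / sqrt((K/N) (1 - K/N) / n)`.  Raw z-scores are then
#' standardized by their empirical mean and standard deviation across the
#' subnetwork, and the upper-tail standard normal probability of the
#' standardized value is reported, so over-connected nodes (relative to
#' the batch) get small p-values.  Both raw and standardized z are
#' returned so either convention can be inspected.
#'
#' Nodes with degenerate store counts (`K = 0` or `K = N`) have no defined
#' z; they receive the worst (largest) p in the batch and are flagged.
#' When the batch standard deviation is 0 every p is 0.5.
#'
#' @param k Integer vector: per-node interaction (unique-pair) counts in
#'   the subnetwork.
#' @param n Integer: total interaction pairs in the subnetwork.
#' @param K Integer vector: per-node pair counts in the organism-filtered
#'   store.
#' @param N Integer: total pairs in the organism-filtered store.
#' @return Data frame with columns `z_raw`, `z_std`, `p`, `flagged`.
#' @export
node_significance <- function(k, n, K, N) {
  stopifnot(length(k) == length(K), N > 0, n > 0)
  valid <- K > 0 & K < N
  z_raw <- rep(NA_real_, length(k))
  q <- K[valid] / N
  z_raw[valid] <- (k[valid] / n - q) / sqrt(q * (1 - q) / n)
  p <- rep(NA_real_, length(k))
  z_std <- rep(NA_real_, length(k))
  if (any(valid)) {
    mu <- mean(z_raw[valid])
    sdv <- stats::sd(z_raw[valid])
    if (is.na(sdv) || sdv == 0) {
      z_std[valid] <- 0
      p[valid] <- 0.5
    } else {
      z_std[valid] <- (z_raw[valid] - mu) / sdv
      p[valid] <- stats::pnorm(z_std[valid], lower.tail = FALSE)
    }
    p[!valid] <- max(p[valid])
  } else {
    p[] <- 0.5
  }
  data.frame(z_raw = z_raw, z_std = z_std, p = p, flagged = !valid)
}
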