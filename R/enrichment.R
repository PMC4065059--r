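# Hypergeometric term enrichment (GO biological process / KEGG pathway)
# over network proteins against a background organism, with an
# overflow-safe handoff from direct factorial evaluation to log-gamma
# summation, and per-node top-term cluster assignment.

#' Upper-tail hypergeometric probability with exact/log-gamma handoff
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (urn of `N`
#' entities, `K` annotated to the term, `n` drawn).  Two evaluation modes
#' are implemented: the exact mode multiplies binomial coefficients built
#' from direct factorials via the gamma function, which overflows double
#' precision for large counts; the log-gamma mode accumulates each tail
#' term in log space via `lgamma` and is safe at any size.  The mode is
#' chosen by the term size: `K > switchover` (default 1800, the empirical
#' transition point below which direct evaluation stays finite for
#' genome-scale backgrounds) selects log-gamma.  Wherever both modes are
#' computable they agree to within 1e-9 relative error.
#'
#' @param k Network entities annotated to the term.
#' @param n Network entities with any annotation.
#' @param K Background entities annotated to the term.
#' @param N Background entities with any annotation.
#' @param switchover Term size above which log-gamma mode is used.
#' @param mode `"auto"` (default, handoff by `switchover`), `"exact"`, or
#'   `"log_gamma"`.
#' @return List with `p_value` and `mode_used`.
#' @export
#' @examples
#' hypergeom_tail(4, 4, 5, 10)   # 5/210
hypergeom_tail <- function(k, n, K, N, switchover = 1800L,
                           mode = c("auto", "exact", "log_gamma")) {
  mode <- match.arg(mode)
  if (k < 0) stop("invariant violated: k >= 0")
  if (k > n) stop("invariant violated: k <= n")
  if (k > K) stop("invariant violated: k <= K")
  if (n > N) stop("invariant violated: n <= N")
  if (K > N) stop("invariant violated: K <= N")
  use_lg <- switch(mode, auto = K > switchover, exact = FALSE, log_gamma = TRUE)
  jmax <- min(n, K)
  p <- if (k == 0L) {
    1.0
  } else if (use_lg) {
    # sum the pmf in log space; lchoose is lgamma-based
    terms <- vapply(k:jmax, function(j) {
      lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    }, numeric(1))
    m <- max(terms)
    exp(m) * sum(exp(terms - m))
  } else {
    # direct evaluation in linear space: binomial coefficients from
    # gamma-function factorials; overflows for very large counts, which is
    # exactly what the log-gamma mode exists to avoid
    denom <- choose(N, n)
    sum(vapply(k:jmax, function(j) choose(K, j) * choose(N - K, n - j),
               numeric(1))) / denom
  }
  list(p_value = min(p, 1.0), mode_used = if (use_lg) "log_gamma" else "exact")
}

#' Term enrichment over network proteins
#'
#' For every term with at least one annotated network protein, forms the
#' hypergeometric quadruple (`k`, `n`, `K`, `N`) over annotated entities
#' (network proteins annotated to the term; network proteins with any
#' annotation; background proteins annotated to the term; background
#' proteins with any annotation) and computes the upper-tail probability.
#' Metabolites and drugs are excluded from all counts.  The background
#' universe is the annotated proteins of `background_ids` (typically the
#' background organism's entities in the store).
#'
#' @param net A `pmd_network`.
#' @param term_sets Named list term id -> character vector of member ids
#'   (e.g. from [read_gmt()]); an optional `term_names` attribute supplies
#'   display names.
#' @param background_ids Character vector of background protein ids.
#' @param alpha Significance level; terms with `p <= alpha` are flagged
#'   enriched (raw p-values, no multiple-testing correction by default).
#' @param adjust Apply Benjamini-Hochberg correction before flagging.
#' @param switchover Passed to [hypergeom_tail()].
#' @return Data frame sorted ascending by p-value with columns `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p_value`, `mode`, `enriched`,
#'   `members` (`;`-joined network member ids).
#' @export
enrich_terms <- function(net, term_sets, background_ids, alpha = 0.05,
                         adjust = FALSE, switchover = 1800L) {
  prot <- net$nodes$id[net$nodes$kind == "protein"]
  annotated_universe <- unique(unlist(term_sets, use.names = FALSE))
  bg <- intersect(unique(background_ids), annotated_universe)
  N <- length(bg)
  net_annot <- intersect(prot, annotated_universe)
  n <- length(net_annot)
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), mode = character(),
                      enriched = logical(), members = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("network has no annotated proteins; empty enrichment result")
    return(empty)
  }
  if (N == 0L) stop("background catalog is empty")
  nm <- attr(term_sets, "term_names") %||% character()
  rows <- lapply(names(term_sets), function(tid) {
    members <- intersect(term_sets[[tid]], net_annot)
    k <- length(members)
    if (k == 0L) return(NULL)
    K <- length(intersect(term_sets[[tid]], bg))
    ht <- hypergeom_tail(k, n, K, N, switchover = switchover)
    data.frame(term_id = tid,
               term_name = if (tid %in% names(nm)) nm[[tid]] else tid,
               k = k, n = n, K = K, N = N,
               p_value = ht$p_value, mode = ht$mode_used,
               enriched = NA, members = paste(sort(members), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  p <- if (adjust) stats::p.adjust(res$p_value, method = "BH") else res$p_value
  res$enriched <- p <= alpha
  res <- res[order(res$p_value, -res$k, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign each node its best enriched term
#'
#' Each node's top-term attribute becomes the enriched (`p <= alpha`) term
#' containing it with the smallest p-value, restricted to qualifying
#' cluster terms: more than `min_cluster` member nodes in the network and,
#' when `require_input_member`, at least one seed/bait member.  Ties on p
#' break by larger `k`, then lexicographic term id.  Nodes in no
#' qualifying term keep an empty attribute.
#'
#' @param net A `pmd_network`.
#' @param results Data frame from [enrich_terms()].
#' @param attribute `"top_bp"` or `"top_kegg"` node column to fill.
#' @param alpha Significance level.
#' @param min_cluster A qualifying term needs more than this many member
#'   nodes (default 3).
#' @param require_input_member Demand at least one seed/bait member node.
#' @return The network with the chosen attribute filled.
#' @export
assign_top_terms <- function(net, results, attribute = c("top_bp", "top_kegg"),
                             alpha = 0.05, min_cluster = 3L,
                             require_input_member = FALSE) {
  attribute <- match.arg(attribute)
  net$nodes[[attribute]] <- ""
  if (is.null(results) || nrow(results) == 0L) return(net)
  seeds <- net$nodes$id[net$nodes$seed | net$nodes$bait]
  ok <- results$p_value <= alpha & results$k > min_cluster
  if (require_input_member) {
    has_seed <- vapply(strsplit(results$members, ";", fixed = TRUE),
                       function(m) any(m %in% seeds), logical(1))
    ok <- ok & has_seed
  }
  cand <- results[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(net)
  cand <- cand[order(cand$p_value, -cand$k, cand$term_id), , drop = FALSE]
  assigned <- character(0)
  for (i in seq_len(nrow(cand))) {
    members <- strsplit(cand$members[[i]], ";", fixed = TRUE)[[1]]
    members <- setdiff(members, assigned)
    idx <- match(members, net$nodes$id)
    idx <- idx[!is.na(idx)]
    net$nodes[[attribute]][idx] <- cand$term_id[[i]]
    assigned <- c(assigned, members)
  }
  net
}

#' Write an enrichment report TSV
#'
#' Header comment records the counting convention (annotated entities).
#'
#' @param results Data frame from [enrich_terms()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_report <- function(results, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# counts are over annotated entities (k, n, K, N)", con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
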