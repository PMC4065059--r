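# Seeded network expansion, scoring and the ordered filter pipeline.
# A pmd_network is the central artifact: nodes and edges with display and
# confidence attributes, handed between builder, enrichment, topology and
# the XGMML writer.

.NODE_COLORS <- c(bait = "#FF0000", seed = "#0000FF", level1 = "#00FF00",
                  level2 = "#FFA500", level3 = "#800080",
                  metabolite = "#FFFF00", drug = "#FFFF00",
                  up = "#FF0000", down = "#00FF00", background = "#C0C0C0")

.NODE_SHAPES <- c(protein = "ELLIPSE", metabolite = "RECTANGLE",
                  drug = "TRIANGLE")

.level_color <- function(kind, level, is_bait, is_seed) {
  col <- rep(.NODE_COLORS[["background"]], length(kind))
  col[level == 1L] <- .NODE_COLORS[["level1"]]
  col[level == 2L] <- .NODE_COLORS[["level2"]]
  col[level >= 3L] <- .NODE_COLORS[["level3"]]
  col[is_seed] <- .NODE_COLORS[["seed"]]
  col[kind %in% c("metabolite", "drug")] <- .NODE_COLORS[["metabolite"]]
  col[is_bait] <- .NODE_COLORS[["bait"]]
  col
}

#' Construct a pmd_network
#'
#' @param nodes Data frame with at least an `id` column; missing attribute
#'   columns are filled with defaults.
#' @param edges Data frame with at least `id_a`, `id_b`; every endpoint
#'   must be a node.
#' @return An object of class `pmd_network`.
#' @export
pmd_network <- function(nodes, edges) {
  node_defaults <- list(kind = "protein", organism = "", symbol = "",
                        seed = FALSE, bait = FALSE, level = NA_integer_,
                        cc = "", fold_change = NA_real_, regulation = "none",
                        degree = NA_integer_, p_value = NA_real_,
                        z_raw = NA_real_, z_std = NA_real_, p_flagged = FALSE,
                        top_bp = "", top_kegg = "",
                        size = NA_real_, color = "", shape = "")
  for (nm in names(node_defaults)) {
    if (!nm %in% names(nodes)) nodes[[nm]] <- rep(node_defaults[[nm]], nrow(nodes))
  }
  edge_defaults <- list(evidence = "experimental", pmids = "", n_pubs = 0L,
                        methods = "", sources = "", class_total = NA_integer_,
                        class_label = "unclassified", width = 0.5,
                        fsw = NA_real_, novel = FALSE)
  for (nm in names(edge_defaults)) {
    if (!nm %in% names(edges)) edges[[nm]] <- rep(edge_defaults[[nm]], nrow(edges))
  }
  if (nrow(edges) > 0L) {
    bad <- !(edges$id_a %in% nodes$id) | !(edges$id_b %in% nodes$id)
    if (any(bad)) stop("edge endpoint(s) not in node set: ",
                       paste(unique(c(edges$id_a[bad], edges$id_b[bad])), collapse = ", "))
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges$pair <- if (nrow(edges)) pair_id(edges$id_a, edges$id_b) else character()
  edges <- edges[order(edges$pair), , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "pmd_network"
  update_degrees(out)
}

#' @export
print.pmd_network <- function(x, ...) {
  cat("pmd_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Recompute the degree attribute (and degree-driven display size)
#' @param net A `pmd_network`.
#' @return The network with `degree` equal to incident edge count.
#' @export
update_degrees <- function(net) {
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$id_a, net$edges$id_b))
    deg[names(tab)] <- as.integer(tab)
  }
  net$nodes$degree <- unname(deg[net$nodes$id])
  # gradient of node sizes by connectivity makes hubs stand out;
  # expression-scaled sizes (annotate_expression) override this later.
  base <- 20 + 5 * net$nodes$degree
  keep <- !is.na(net$nodes$fold_change) & net$nodes$regulation %in% c("up", "down")
  net$nodes$size <- ifelse(keep, net$nodes$size, base)
  net
}

# Score a set of store pairs into network edge rows using the store's
# publication table (pmid -> interaction count; unknown pmid -> NA -> HT)
# and the catalog's selected-CC sets for co-localization.
.score_edges <- function(pairs, store) {
  if (nrow(pairs) == 0L) {
    out <- pairs
    out$class_total <- integer(); out$class_label <- character()
    out$width <- numeric(); out$novel <- logical()
    return(out)
  }
  pubs <- store$publications
  cc <- if (!is.null(store$catalog)) store$catalog$cc_terms else list()
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pmids <- strsplit(pairs$pmids[[i]], ";", fixed = TRUE)[[1]]
    pmids <- pmids[nzchar(pmids)]
    counts <- if (is.null(pubs)) rep(NA_integer_, length(pmids)) else
      pubs$interaction_count[match(pmids, pubs$pmid)]
    same_cc <- length(intersect(
      cc[[pairs$id_a[[i]]]] %||% character(),
      cc[[pairs$id_b[[i]]]] %||% character())) > 0L
    class_score(pairs$evidence[[i]] == "experimental", counts, same_cc)
  })
  pairs$class_total <- vapply(res, `[[`, integer(1), "total")
  pairs$class_label <- vapply(res, `[[`, character(1), "label")
  pairs$width <- vapply(res, `[[`, numeric(1), "width")
  pairs$novel <- FALSE
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand seed entities into an induced, scored subnetwork
#'
#' Breadth-first frontier growth from the seeds to `depth` (1-3) using the
#' store's neighbor sets; metabolite and drug partners join the frontier
#' only when the corresponding flag is on (seed entities are always kept,
#' whatever their kind).  The edge set is the induced subgraph: every
#' non-self store pair among the retained nodes, not only traversal edges.
#' Each edge carries its Class score, width and FSWeight; each node its
#' level (seeds 0), degree, kind, selected CC terms, display color and
#' shape.  When `background_organism` is given, node significance
#' p-values are computed against the organism-filtered store.
#'
#' @param store A `pmd_store` (with publications/catalog for scoring).
#' @param seeds Character vector of seed accessions.
#' @param depth Expansion level, 1 to 3.
#' @param include_metabolites,include_drugs Frontier kind flags.
#' @param background_organism Optional taxon label for node p-values.
#' @return A `pmd_network`.  Seeds absent from the store are kept as
#'   isolated level-0 nodes and listed in the `unmatched_seeds` attribute.
#' @export
expand <- function(store, seeds, depth = 1L, include_metabolites = FALSE,
                   include_drugs = FALSE, background_organism = NULL) {
  if (length(seeds) == 0L) stop("configuration error: empty seed list")
  if (!depth %in% 1:3) stop("depth must be 1, 2 or 3")
  seeds <- unique(seeds)
  known <- unique(c(store$pairs$id_a, store$pairs$id_b))
  unmatched <- setdiff(seeds, known)

  level <- stats::setNames(rep(0L, length(seeds)), seeds)
  frontier <- seeds
  for (d in seq_len(depth)) {
    nxt <- character()
    for (id in frontier) {
      nxt <- c(nxt, store_neighbors(store, id, include_metabolites, include_drugs))
    }
    nxt <- setdiff(unique(nxt), names(level))
    if (length(nxt) == 0L) break
    level[nxt] <- d
    frontier <- nxt
  }
  ids <- names(level)

  p <- store$pairs
  keep <- p$id_a %in% ids & p$id_b %in% ids & !p$self
  edges <- .score_edges(p[keep, c("id_a", "id_b", "kind_a", "kind_b",
                                  "evidence", "pmids", "n_pubs",
                                  "methods", "sources"), drop = FALSE], store)

  ent <- store$entities
  kind <- entity_kind(ids)
  hit <- match(ids, ent$id)
  organism <- ifelse(is.na(hit), "", ent$organism[hit])
  cc <- if (!is.null(store$catalog)) store$catalog$cc_terms else list()
  cc_str <- vapply(ids, function(i) paste(sort(cc[[i]] %||% character()), collapse = ";"),
                   character(1))
  nodes <- data.frame(
    id = ids, kind = kind, organism = organism,
    seed = ids %in% seeds, bait = FALSE, level = unname(level[ids]),
    cc = unname(cc_str), stringsAsFactors = FALSE
  )
  nodes$color <- .level_color(nodes$kind, nodes$level, nodes$bait, nodes$seed)
  nodes$shape <- unname(.NODE_SHAPES[nodes$kind])

  net <- pmd_network(nodes, edges)
  net$edges$fsw <- fsw_edge_scores(net$edges, nodes = net$nodes$id)
  if (!is.null(background_organism)) {
    net <- score_node_significance(net, store, background_organism)
  }
  attr(net, "unmatched_seeds") <- unmatched
  net
}

#' Attach node significance p-values to a network
#'
#' `k` counts each node's unique non-self pairs inside the network, `n`
#' the network's pair total, `K` and `N` the analogous counts in the
#' store restricted to `background_organism` (see [node_significance()]).
#'
#' @param net A `pmd_network`.
#' @param store A `pmd_store`.
#' @param background_organism Taxon label filtering the store.
#' @return The network with `p_value`, `z_raw`, `z_std`, `p_flagged` node
#'   columns filled.
#' @export
score_node_significance <- function(net, store, background_organism) {
  bg <- store_filter_organism(store, background_organism)
  bgp <- bg$pairs[!bg$pairs$self, , drop = FALSE]
  N <- nrow(bgp)
  n <- nrow(net$edges)
  if (N == 0L || n == 0L) {
    warning("no pairs available for node significance (N=", N, ", n=", n, ")")
    return(net)
  }
  k <- net$nodes$degree
  Ktab <- table(c(bgp$id_a, bgp$id_b))
  K <- as.integer(Ktab[net$nodes$id]); K[is.na(K)] <- 0L
  sig <- node_significance(k, n, K, N)
  net$nodes$z_raw <- sig$z_raw
  net$nodes$z_std <- sig$z_std
  net$nodes$p_value <- sig$p
  net$nodes$p_flagged <- sig$flagged
  net
}

#' Connect a bait entity to its screened preys
#'
#' Adds the bait as a level-0 seed node (colored as bait).  Store-evidenced
#' pairs between the bait and network nodes enter as regularly scored
#' edges; each prey without store evidence gets a novel bait-prey edge
#' with zero publications, class E and the novel flag set.  A prey equal
#' to the bait is skipped with a warning.
#'
#' @param net A `pmd_network`.
#' @param bait Bait accession.
#' @param preys Character vector of prey accessions, all network nodes.
#' @param store The `pmd_store` used to build `net`.
#' @return The augmented network.
#' @export
attach_bait <- function(net, bait, preys, store) {
  stopifnot(all(preys %in% net$nodes$id))
  if (bait %in% preys) {
    warning("bait equals prey '", bait, "'; self-edge skipped")
    preys <- setdiff(preys, bait)
  }
  if (!bait %in% net$nodes$id) {
    bn <- data.frame(id = bait, kind = entity_kind(bait), organism = "",
                     symbol = "", seed = TRUE, bait = TRUE, level = 0L,
                     cc = "", regulation = "none",
                     color = .NODE_COLORS[["bait"]],
                     shape = unname(.NODE_SHAPES[[entity_kind(bait)]]),
                     stringsAsFactors = FALSE)
    net$nodes <- .rbind_fill(net$nodes, bn)
  } else {
    i <- match(bait, net$nodes$id)
    net$nodes$bait[i] <- TRUE
    net$nodes$seed[i] <- TRUE
    net$nodes$level[i] <- 0L
    net$nodes$color[i] <- .NODE_COLORS[["bait"]]
  }

  node_ids <- net$nodes$id
  sp <- store$pairs
  evidenced <- sp[!sp$self &
                    ((sp$id_a == bait & sp$id_b %in% node_ids) |
                       (sp$id_b == bait & sp$id_a %in% node_ids)), , drop = FALSE]
  new_pairs <- setdiff(pair_id(evidenced$id_a, evidenced$id_b), net$edges$pair)
  if (length(new_pairs) > 0L) {
    add <- evidenced[pair_id(evidenced$id_a, evidenced$id_b) %in% new_pairs,
                     c("id_a", "id_b", "kind_a", "kind_b", "evidence",
                       "pmids", "n_pubs", "methods", "sources"), drop = FALSE]
    add <- .score_edges(add, store)
    net$edges <- .rbind_fill(net$edges, add)
  }
  store_partners <- unique(c(evidenced$id_a, evidenced$id_b))
  novel_preys <- setdiff(preys, store_partners)
  if (length(novel_preys) > 0L) {
    nov <- data.frame(id_a = pmin(bait, novel_preys), id_b = pmax(bait, novel_preys),
                      evidence = "experimental", pmids = "", n_pubs = 0L,
                      methods = "two-hybrid", sources = "user",
                      class_total = 4L, class_label = "E", width = 0.5,
                      fsw = NA_real_, novel = TRUE, stringsAsFactors = FALSE)
    net$edges <- .rbind_fill(net$edges, nov)
  }
  out <- pmd_network(net$nodes, net$edges)
  out$edges$fsw <- fsw_edge_scores(out$edges, nodes = out$nodes$id)
  for (at in c("unmatched_seeds", "filter_report")) {
    if (!is.null(attr(net, at))) attr(out, at) <- attr(net, at)
  }
  out
}

.rbind_fill <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) {
    b[[nm]] <- rep(switch(class(a[[nm]])[1],
                          character = "", integer = NA_integer_,
                          numeric = NA_real_, logical = FALSE, NA), nrow(b))
  }
  rbind(a, b[, names(a), drop = FALSE])
}

#' Apply the ordered confidence filter pipeline
#'
#' Filters run in a fixed order: (i) Class score, (ii) node p-value,
#' (iii) deletion of nodes with connectivity degree 0 and 1, and (iv) FSW
#' score.  Each stage only removes elements; removing a node deletes its
#' incident edges, and degrees are refreshed between stages so the degree
#' prune sees post-filter connectivity.  A per-stage removal report is
#' attached as the `filter_report` attribute.
#'
#' @param net A `pmd_network` with scores present.
#' @param class_cutoff Minimal class label to keep (`"A"`..`"E"`);
#'   unclassified edges are always removed when this filter is active.
#' @param pvalue_cutoff Nodes with p-value above this are removed.
#' @param delete_degree_01 Run the single-pass degree 0/1 prune.
#' @param fsw_cutoff Edges with FSW below this are removed.
#' @param iterate_prune Iterate the degree prune to a 2-core instead of
#'   the default single pass.
#' @param protect_seeds Exempt seed/bait nodes from node-removing stages
#'   (off by default).
#' @return The filtered network with a `filter_report` attribute (data
#'   frame of per-stage node/edge removal counts).
#' @export
apply_filters <- function(net, class_cutoff = NULL, pvalue_cutoff = NULL,
                          delete_degree_01 = FALSE, fsw_cutoff = NULL,
                          iterate_prune = FALSE, protect_seeds = FALSE) {
  report <- data.frame(stage = character(), nodes_removed = integer(),
                       edges_removed = integer(), stringsAsFactors = FALSE)
  note <- function(stage, n0, e0) {
    report <<- rbind(report, data.frame(
      stage = stage, nodes_removed = n0 - nrow(net$nodes),
      edges_removed = e0 - nrow(net$edges), stringsAsFactors = FALSE))
  }

  if (!is.null(class_cutoff)) {
    n0 <- nrow(net$nodes); e0 <- nrow(net$edges)
    keep <- class_rank(net$edges$class_label) >= class_rank(class_cutoff)
    net$edges <- net$edges[keep, , drop = FALSE]
    net <- update_degrees(net)
    note("class_score", n0, e0)
  }
  if (!is.null(pvalue_cutoff)) {
    n0 <- nrow(net$nodes); e0 <- nrow(net$edges)
    drop <- !is.na(net$nodes$p_value) & net$nodes$p_value > pvalue_cutoff
    if (protect_seeds) drop <- drop & !(net$nodes$seed | net$nodes$bait)
    net <- .remove_nodes(net, net$nodes$id[drop])
    note("p_value", n0, e0)
  }
  if (isTRUE(delete_degree_01)) {
    n0 <- nrow(net$nodes); e0 <- nrow(net$edges)
    net <- prune_low_degree(net, iterate = iterate_prune,
                            protect_seeds = protect_seeds)
    note("degree_01", n0, e0)
  }
  if (!is.null(fsw_cutoff)) {
    n0 <- nrow(net$nodes); e0 <- nrow(net$edges)
    keep <- !is.na(net$edges$fsw) & net$edges$fsw >= fsw_cutoff
    net$edges <- net$edges[keep, , drop = FALSE]
    net <- update_degrees(net)
    note("fsw", n0, e0)
  }
  attr(net, "filter_report") <- report
  net
}

.remove_nodes <- function(net, ids) {
  if (length(ids) == 0L) return(update_degrees(net))
  net$nodes <- net$nodes[!net$nodes$id %in% ids, , drop = FALSE]
  net$edges <- net$edges[!(net$edges$id_a %in% ids | net$edges$id_b %in% ids), ,
                         drop = FALSE]
  update_degrees(net)
}

#' Delete nodes of connectivity degree 0 and 1
#'
#' A single simultaneous pass: every node whose degree at entry is 0 or 1
#' is removed, together with incident edges.  The pass is deliberately not
#' iterated to a 2-core (a former degree-2 node left with degree 1 by the
#' pass survives); set `iterate = TRUE` for the 2-core variant.  Seeds and
#' bait are pruned like any other node unless `protect_seeds`.
#'
#' @param net A `pmd_network` with current degrees.
#' @param iterate Repeat passes until no degree 0/1 node remains.
#' @param protect_seeds Exempt seed/bait nodes.
#' @return The pruned network.
#' @export
prune_low_degree <- function(net, iterate = FALSE, protect_seeds = FALSE) {
  repeat {
    drop <- net$nodes$degree <= 1L
    if (protect_seeds) drop <- drop & !(net$nodes$seed | net$nodes$bait)
    if (!any(drop)) break
    net <- .remove_nodes(net, net$nodes$id[drop])
    if (!iterate) break
  }
  net
}

#' Read a two-column fold-change table
#'
#' One entry per line: an identifier token (accession or gene symbol) and
#' a signed fold change, separated by tabs or whitespace.
#'
#' @param path File path.
#' @return Data frame with columns `token` (character) and `fold_change`
#'   (numeric).
#' @export
read_foldchange_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tok <- character(length(lines)); fc <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    if (length(f) < 2L) stop("fold-change table format error at line ", i,
                             ": need identifier and fold change")
    val <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(val)) stop("fold-change table format error at line ", i,
                         ": non-numeric fold change '", f[[2]], "'")
    tok[[i]] <- f[[1]]; fc[[i]] <- val
  }
  data.frame(token = tok, fold_change = fc, stringsAsFactors = FALSE)
}

#' Annotate a network with expression fold changes
#'
#' Matched nodes (by accession, then by gene symbol) receive their fold
#' change, a regulation call with closed boundaries (up iff
#' `fc >= up_cutoff`, down iff `fc <= down_cutoff`, else unchanged), the
#' up/down display colors (red/green) overriding level colors, and a
#' display size proportional to |fold change| under
#' `size_scaling = "proportional_abs_fc"`.  Unmatched nodes keep
#' regulation `"none"`.  Duplicate identifiers in the table: last value
#' wins, with a warning.
#'
#' @param net A `pmd_network`.
#' @param table Data frame from [read_foldchange_table()].
#' @param up_cutoff Fold change at/above which a node is up-regulated
#'   (default 1.3, the proteome convention; metabolome studies typically
#'   use 1.2).
#' @param down_cutoff Fold change at/below which a node is down-regulated
#'   (default -1.3).
#' @param size_scaling `"proportional_abs_fc"` or `"fixed"`.
#' @return The annotated network.
#' @export
annotate_expression <- function(net, table, up_cutoff = 1.3,
                                down_cutoff = -1.3,
                                size_scaling = c("proportional_abs_fc", "fixed")) {
  size_scaling <- match.arg(size_scaling)
  stopifnot(up_cutoff > 0, down_cutoff < 0)
  if (anyDuplicated(table$token)) {
    warning("duplicate identifier(s) in fold-change table; last value wins: ",
            paste(unique(table$token[duplicated(table$token)]), collapse = ", "))
    table <- table[!duplicated(table$token, fromLast = TRUE), , drop = FALSE]
  }
  hit <- match(net$nodes$id, table$token)
  miss <- is.na(hit) & nzchar(net$nodes$symbol)
  hit[miss] <- match(net$nodes$symbol[miss], table$token)
  matched <- !is.na(hit)
  fc <- table$fold_change[hit[matched]]
  net$nodes$fold_change[matched] <- fc
  reg <- ifelse(fc >= up_cutoff, "up", ifelse(fc <= down_cutoff, "down", "unchanged"))
  net$nodes$regulation <- "none"
  net$nodes$regulation[matched] <- reg
  net$nodes$color[matched & net$nodes$regulation == "up"] <- .NODE_COLORS[["up"]]
  net$nodes$color[matched & net$nodes$regulation == "down"] <- .NODE_COLORS[["down"]]
  if (size_scaling == "proportional_abs_fc") {
    net$nodes$size[which(matched)[reg %in% c("up", "down")]] <-
      30 * abs(fc[reg %in% c("up", "down")])
  }
  net
}
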