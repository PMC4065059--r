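# Seeded synthetic-fixture generators: interaction stores with scale-free
# topology and controllable evidence composition, annotation catalogs,
# publication tables, seed lists and fold-change tables.  Everything is
# deterministic given the spec's rng_seed, and every generated file parses
# through the package's own readers, so the whole pipeline is testable
# without any database download.

#' Specification of a synthetic interaction store
#'
#' Defaults describe a desk-scale store that mimics the statistical
#' structure of an integrated interaction database: a scale-free protein
#' interaction graph from preferential attachment, a mostly-experimental
#' evidence mix, roughly 1.5 publications per pair with about a third of
#' publications high-throughput, small term vocabularies (kept small so
#' enrichment enumeration oracles stay exact), and a tunable coupling
#' between evidence quality and shared-neighbor counts.
#'
#' @param n_proteins,n_metabolites,n_drugs Entity counts.
#' @param attachment_m Preferential-attachment edges per new node.
#' @param evidence_mix Named proportions over `experimental`/`predicted`
#'   (must sum to 1).
#' @param pub_rate Mean publications per pair (Poisson).
#' @param ht_fraction Fraction of publications describing more than 500
#'   interactions.
#' @param cc_vocab,bp_vocab,kegg_vocab Vocabulary sizes.
#' @param annotation_density Mean BP/KEGG terms per entity.
#' @param evidence_fsw_coupling In [0, 1]: how strongly multi-paper
#'   experimental evidence concentrates on pairs with many shared
#'   neighbors (0 = independent).
#' @param organism Taxon label of the store.
#' @param rng_seed Integer seed; the generator is fully deterministic
#'   given the seed.
#' @return A list of class `synthetic_store_spec`.
#' @export
synthetic_store_spec <- function(n_proteins = 200L, n_metabolites = 20L,
                                 n_drugs = 10L, attachment_m = 2L,
                                 evidence_mix = c(experimental = 0.7, predicted = 0.3),
                                 pub_rate = 1.5, ht_fraction = 0.3,
                                 cc_vocab = 12L, bp_vocab = 30L, kegg_vocab = 20L,
                                 annotation_density = 3,
                                 evidence_fsw_coupling = 0,
                                 organism = "orgA", rng_seed = 1L) {
  stopifnot(n_proteins >= 0, n_metabolites >= 0, n_drugs >= 0,
            abs(sum(evidence_mix) - 1) < 1e-9,
            evidence_fsw_coupling >= 0, evidence_fsw_coupling <= 1)
  spec <- list(n_proteins = as.integer(n_proteins),
               n_metabolites = as.integer(n_metabolites),
               n_drugs = as.integer(n_drugs),
               attachment_m = as.integer(attachment_m),
               evidence_mix = evidence_mix, pub_rate = pub_rate,
               ht_fraction = ht_fraction, cc_vocab = as.integer(cc_vocab),
               bp_vocab = as.integer(bp_vocab), kegg_vocab = as.integer(kegg_vocab),
               annotation_density = annotation_density,
               evidence_fsw_coupling = evidence_fsw_coupling,
               organism = organism, rng_seed = as.integer(rng_seed))
  class(spec) <- "synthetic_store_spec"
  spec
}

.sid <- function(prefix, i, width = 4) sprintf("%s%0*d", prefix, width, i)

#' Generate a synthetic interaction store
#'
#' Builds a scale-free protein graph by preferential attachment, attaches
#' metabolites and drugs to degree-weighted proteins, samples evidence
#' types, publications (with high-throughput counts above 500) and
#' annotations per the spec, and assembles everything into a deduplicated
#' `pmd_store` with catalog and publication table.  With
#' `evidence_fsw_coupling` near 1, pairs sharing many neighbors receive
#' multi-paper experimental evidence, so top-FSW edges become enriched in
#' the best classes.
#'
#' @param spec A [synthetic_store_spec()].
#' @return List with `store` (a `pmd_store`), `records` (the raw record
#'   data frame), `publications`, `catalog` and `spec`.
#' @export
synth_store <- function(spec = synthetic_store_spec()) {
  if (spec$n_proteins == 0L) stop("need at least one protein")
  set.seed(spec$rng_seed)
  org <- spec$organism
  prot <- .sid("P", seq_len(spec$n_proteins))

  g <- igraph::sample_pa(spec$n_proteins, m = spec$attachment_m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(id_a = prot[el[, 1]], id_b = prot[el[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
  edges <- edges[!duplicated(pair_id(edges$id_a, edges$id_b)), , drop = FALSE]

  # metabolites/drugs attach to degree-weighted proteins
  deg <- igraph::degree(g)
  attach_kind <- function(ids) {
    do.call(rbind, lapply(ids, function(id) {
      k <- sample(1:3, 1)
      partners <- sample(prot, k, prob = deg + 1)
      data.frame(id_a = id, id_b = partners, stringsAsFactors = FALSE)
    }))
  }
  mets <- if (spec$n_metabolites > 0L) .sid("HMDB", seq_len(spec$n_metabolites), 7) else character()
  drugs <- if (spec$n_drugs > 0L) .sid("DB", seq_len(spec$n_drugs), 5) else character()
  if (length(mets) > 0L) edges <- rbind(edges, attach_kind(mets))
  if (length(drugs) > 0L) edges <- rbind(edges, attach_kind(drugs))
  n_edges <- nrow(edges)

  # publication pool
  n_pubs <- max(20L, ceiling(n_edges * spec$pub_rate / 3))
  pubs <- data.frame(
    pmid = as.character(seq(10000001L, length.out = n_pubs)),
    interaction_count = ifelse(stats::runif(n_pubs) < spec$ht_fraction,
                               sample(501:3000, n_pubs, replace = TRUE),
                               sample(1:500, n_pubs, replace = TRUE)),
    stringsAsFactors = FALSE)
  non_ht <- pubs$pmid[!is_high_throughput(pubs$interaction_count)]

  # base evidence per pair
  evidence <- sample(names(spec$evidence_mix), n_edges, replace = TRUE,
                     prob = spec$evidence_mix)
  npub <- stats::rpois(n_edges, spec$pub_rate)

  # couple evidence quality to shared-neighbor counts
  if (spec$evidence_fsw_coupling > 0 && n_edges > 0L) {
    adj <- adjacency_list(edges)
    cn <- vapply(seq_len(n_edges), function(i) {
      length(intersect(adj[[edges$id_a[[i]]]], adj[[edges$id_b[[i]]]]))
    }, numeric(1))
    r <- rank(cn, ties.method = "average") / n_edges
    boost <- stats::runif(n_edges) < spec$evidence_fsw_coupling * r^2
    evidence[boost] <- "experimental"
    npub[boost] <- pmax(npub[boost], 2L)
  }

  methods_pool <- c("two hybrid", "affinity chromatography", "pull down",
                    "coimmunoprecipitation", "x-ray crystallography",
                    "computational prediction")
  sources_pool <- c("BioGRID", "IntAct", "DIP", "MINT", "HPRD",
                    "DrugBank", "HMDB", "YMDB", "ECMDB")
  rec_rows <- lapply(seq_len(n_edges), function(i) {
    k <- npub[[i]]
    pmids <- if (k == 0L) "" else {
      drawn <- sample(pubs$pmid, min(k, n_pubs))
      # with any coupling boost, anchor one non-HT paper when available
      if (k >= 2L && spec$evidence_fsw_coupling > 0 && length(non_ht) > 0L &&
          !any(drawn %in% non_ht)) drawn[[1]] <- sample(non_ht, 1)
      drawn
    }
    nsrc <- sample(1:2, 1)
    data.frame(id_a = edges$id_a[[i]], id_b = edges$id_b[[i]],
               organism_a = org, organism_b = org,
               evidence = evidence[[i]],
               method = sample(methods_pool, 1),
               pmid = pmids,
               source_db = sample(sources_pool, length(pmids) * nsrc,
                                  replace = TRUE)[seq_along(pmids)],
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec_rows)
  records$kind_a <- entity_kind(records$id_a)
  records$kind_b <- entity_kind(records$id_b)

  all_ents <- c(prot, mets, drugs)

  # cellular components: popularity-weighted so co-localization happens
  cc_terms <- .sid("CC", seq_len(spec$cc_vocab), 2)
  cc_w <- stats::rexp(spec$cc_vocab) + 0.2
  cc <- stats::setNames(lapply(all_ents, function(e) {
    sort(sample(cc_terms, sample(1:2, 1), prob = cc_w))
  }), all_ents)

  sample_term_sets <- function(vocab, prefix) {
    terms <- .sid(prefix, seq_len(vocab), 3)
    w <- stats::rexp(vocab) + 0.2
    per_ent <- lapply(all_ents, function(e) {
      k <- min(stats::rpois(1, spec$annotation_density), vocab)
      if (k == 0L) character() else sample(terms, k, prob = w)
    })
    sets <- stats::setNames(lapply(terms, function(t) {
      all_ents[vapply(per_ent, function(x) t %in% x, logical(1))]
    }), terms)
    sets <- sets[vapply(sets, length, integer(1)) > 0L]
    attr(sets, "term_names") <- stats::setNames(
      paste(prefix, "term", names(sets)), names(sets))
    sets
  }
  bp <- sample_term_sets(spec$bp_vocab, "BP")
  kegg <- sample_term_sets(spec$kegg_vocab, "KG")

  # symbol map with reviewed/unreviewed tiers and a few ambiguities
  symbol_map <- data.frame(symbol = paste0("GENE", seq_along(prot)),
                           id = prot,
                           reviewed = stats::runif(length(prot)) < 0.85,
                           organism = org, stringsAsFactors = FALSE)
  n_alias <- max(1L, spec$n_proteins %/% 20L)
  alias_idx <- sample(seq_along(prot), n_alias)
  symbol_map <- rbind(symbol_map, data.frame(
    symbol = symbol_map$symbol[alias_idx],
    id = paste0(prot[alias_idx], "T"),
    reviewed = FALSE, organism = org, stringsAsFactors = FALSE))

  ortho_n <- ceiling(0.8 * spec$n_proteins)
  ortholog_map <- data.frame(source_id = prot[seq_len(ortho_n)],
                             source_organism = org,
                             target_id = .sid("Q", seq_len(ortho_n)),
                             target_organism = "orgB",
                             stringsAsFactors = FALSE)

  catalog <- annotation_catalog(cc_terms = cc, bp_terms = bp, kegg_terms = kegg,
                                symbol_map = symbol_map,
                                ortholog_map = ortholog_map)
  store <- pmd_store(records, publications = pubs, catalog = catalog)
  list(store = store, records = records, publications = pubs,
       catalog = catalog, spec = spec)
}

#' Generate seed and fold-change query inputs from a store
#'
#' Seeds are sampled without replacement from the store's proteins.  Fold
#' changes emulate an omics upload: a fraction `fc_fraction` of entries is
#' regulated (split deterministically into up and down by `up_share`, up
#' magnitudes at/above +1.3 and down magnitudes at/below -1.3) and the
#' rest sit in the null band (-1.2, 1.2).
#'
#' @param store A `pmd_store`.
#' @param n_seeds Number of seeds (must not exceed the protein count).
#' @param fc_fraction Fraction of fold-change entries that are regulated.
#' @param up_share Share of regulated entries that are up-regulated
#'   (default 116/211, the shape of a typical encapsulation proteome
#'   upload with 116 up- and 95 down-regulated proteins).
#' @param rng_seed Integer seed.
#' @return List with `seeds` (character) and `fold_changes` (data frame
#'   `token`, `fold_change`).
#' @export
synth_queries <- function(store, n_seeds, fc_fraction = 1, up_share = 116 / 211,
                          rng_seed = 1L) {
  prot <- store$entities$id[store$entities$kind == "protein"]
  prot <- sort(unique(prot))
  if (n_seeds > length(prot)) stop("n_seeds exceeds store protein count")
  set.seed(rng_seed)
  seeds <- sample(prot, n_seeds)
  n_reg <- round(fc_fraction * n_seeds)
  n_up <- round(up_share * n_reg)
  n_down <- n_reg - n_up
  fc <- c(1.3 + stats::rexp(n_up, 0.7),
          -(1.3 + stats::rexp(n_down, 0.7)),
          stats::runif(n_seeds - n_reg, -1.2, 1.2))
  data <- data.frame(token = seeds, fold_change = round(fc, 3),
                     stringsAsFactors = FALSE)
  list(seeds = seeds, fold_changes = data)
}

# ------------------------------------------------------------ file writers

#' Write fixture files in the store's native text formats
#'
#' Emits `interactions.tsv` (native dialect), `publications.tsv`,
#' `bp.gmt`, `kegg.gmt`, `cc.gmt`, `symbols.tsv` and `orthologs.tsv`
#' under `dir`; all of them re-read cleanly through the package readers.
#'
#' @param synth Output of [synth_store()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_store_fixtures <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- synth$records
  out <- rec[, c("id_a", "id_b", "organism_a", "organism_b", "evidence",
                 "method", "pmid", "source_db")]
  for (cl in names(out)) out[[cl]][!nzchar(out[[cl]])] <- "."
  utils::write.table(out, file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(synth$publications, file.path(dir, "publications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(synth$catalog$bp_terms, file.path(dir, "bp.gmt"))
  write_gmt(synth$catalog$kegg_terms, file.path(dir, "kegg.gmt"))
  cc_sets <- .invert_cc(synth$catalog$cc_terms)
  write_gmt(cc_sets, file.path(dir, "cc.gmt"))
  utils::write.table(synth$catalog$symbol_map, file.path(dir, "symbols.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synth$catalog$ortholog_map, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.invert_cc <- function(cc_terms) {
  terms <- sort(unique(unlist(cc_terms, use.names = FALSE)))
  sets <- stats::setNames(lapply(terms, function(t) {
    names(cc_terms)[vapply(cc_terms, function(x) t %in% x, logical(1))]
  }), terms)
  attr(sets, "term_names") <- stats::setNames(terms, terms)
  sets
}

#' Write a GMT-like term-set file
#' @param sets Named list of member vectors with optional `term_names`
#'   attribute.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_names") %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(tid) {
    paste(c(tid, nm[[tid]], sets[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a single-column seed list
#' @param seeds Character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_seed_list <- function(seeds, path) {
  writeLines(seeds, path)
  invisible(path)
}

#' Write a two-column fold-change table
#' @param table Data frame with columns `token`, `fold_change`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_foldchange_table <- function(table, path) {
  writeLines(paste(table$token, table$fold_change, sep = "\t"), path)
  invisible(path)
}
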