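# Shared fixture builders and independent oracles.  Oracles deliberately
# take a different computational route from the package code they check.

make_records <- function(id_a, id_b, evidence = "experimental",
                         method = "two hybrid", pmid = "",
                         source_db = "BioGRID", organism = "orgA") {
  n <- max(length(id_a), length(id_b), length(evidence), length(pmid),
           length(source_db))
  data.frame(id_a = rep_len(id_a, n), id_b = rep_len(id_b, n),
             kind_a = entity_kind(rep_len(id_a, n)),
             kind_b = entity_kind(rep_len(id_b, n)),
             organism_a = rep_len(organism, n), organism_b = rep_len(organism, n),
             evidence = rep_len(evidence, n), method = rep_len(method, n),
             pmid = rep_len(pmid, n), source_db = rep_len(source_db, n),
             stringsAsFactors = FALSE)
}

# Small hand-built store: path P1-P2-P3-P4 plus metabolite and drug
# partners of P2, with publications spanning the HT boundary.
tiny_store <- function() {
  rec <- rbind(
    make_records("P1", "P2", pmid = "11", source_db = "BioGRID"),
    make_records("P1", "P2", pmid = "11", source_db = "IntAct"),
    make_records("P1", "P2", pmid = "22", source_db = "BioGRID"),
    make_records("P2", "P3", pmid = "11"),
    make_records("P3", "P4", evidence = "predicted", pmid = ""),
    make_records("P2", "HMDB0000001", pmid = "33", source_db = "HMDB"),
    make_records("P2", "DB00001", pmid = "", source_db = "DrugBank")
  )
  pubs <- data.frame(pmid = c("11", "22", "33"),
                     interaction_count = c(600L, 10L, 501L),
                     stringsAsFactors = FALSE)
  cc <- list(P1 = "CC01", P2 = c("CC01", "CC02"), P3 = "CC03", P4 = "CC03")
  catalog <- annotation_catalog(cc_terms = cc)
  pmd_store(rec, publications = pubs, catalog = catalog)
}

# --- independent FSWeight oracle on bitmask neighborhoods -----------------
# nodes are 1..n; adjacency is an n x n logical matrix.
oracle_fsw <- function(u, v, adjmat, n_avg) {
  n <- nrow(adjmat)
  Nu <- union(which(adjmat[u, ]), u)
  Nv <- union(which(adjmat[v, ]), v)
  cc <- length(intersect(Nu, Nv))
  if (cc == 0) return(0)
  eu <- length(setdiff(Nu, Nv))
  ev <- length(setdiff(Nv, Nu))
  luv <- max(0, n_avg - (eu + cc))
  lvu <- max(0, n_avg - (ev + cc))
  (2 * cc / (eu + 2 * cc + luv)) * (2 * cc / (ev + 2 * cc + lvu))
}

# --- independent expansion oracle: igraph distances + pair scan ----------
oracle_expand_nodes <- function(store, seeds, depth, include_metabolites,
                                include_drugs) {
  p <- store$pairs[!store$pairs$self, , drop = FALSE]
  keep_kind <- function(kind, id) {
    kind == "protein" | id %in% seeds |
      (kind == "metabolite" & include_metabolites) |
      (kind == "drug" & include_drugs)
  }
  ok <- keep_kind(p$kind_a, p$id_a) & keep_kind(p$kind_b, p$id_b)
  p <- p[ok, , drop = FALSE]
  ids <- unique(c(p$id_a, p$id_b, seeds))
  g <- igraph::graph_from_data_frame(p[, c("id_a", "id_b")], directed = FALSE,
                                     vertices = ids)
  d <- igraph::distances(g, v = seeds[seeds %in% ids])
  reach <- apply(d, 2, min)
  sort(names(reach)[reach <= depth])
}

oracle_induced_pairs <- function(store, ids) {
  p <- store$pairs
  keep <- p$id_a %in% ids & p$id_b %in% ids & !p$self
  sort(p$pair[keep])
}

expect_network_equal <- function(a, b) {
  common_n <- intersect(names(a$nodes), names(b$nodes))
  common_e <- intersect(names(a$edges), names(b$edges))
  for (cl in common_n) {
    if (is.numeric(a$nodes[[cl]])) {
      expect_equal(a$nodes[[cl]], b$nodes[[cl]], tolerance = 1e-12, info = cl)
    } else {
      expect_identical(a$nodes[[cl]], b$nodes[[cl]], info = cl)
    }
  }
  for (cl in common_e) {
    if (is.numeric(a$edges[[cl]])) {
      expect_equal(a$edges[[cl]], b$edges[[cl]], tolerance = 1e-12, info = cl)
    } else {
      expect_identical(a$edges[[cl]], b$edges[[cl]], info = cl)
    }
  }
}
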