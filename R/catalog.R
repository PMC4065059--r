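# Annotation catalogs: identifier/symbol resolution, ortholog mapping,
# selected cellular-component terms and GMT-style term sets.

#' Assemble an annotation catalog
#'
#' @param cc_terms Named list: entity id -> character vector of selected
#'   cellular-component terms (usually the output of [select_cc_terms()]).
#' @param bp_terms,kegg_terms Named list: term id -> character vector of
#'   annotated entity ids; term display names in a `names_map` attribute or
#'   supplied via `term_names`.
#' @param symbol_map Data frame with columns `symbol`, `id`, `reviewed`
#'   (logical; Swiss-Prot-reviewed vs TrEMBL-unreviewed), `organism`.
#' @param ortholog_map Data frame with columns `source_id`,
#'   `source_organism`, `target_id`, `target_organism`.
#' @param term_names Optional named character vector of term display names.
#' @return An object of class `pmd_catalog`.
#' @export
annotation_catalog <- function(cc_terms = list(), bp_terms = list(),
                               kegg_terms = list(), symbol_map = NULL,
                               ortholog_map = NULL, term_names = character()) {
  out <- list(cc_terms = cc_terms, bp_terms = bp_terms, kegg_terms = kegg_terms,
              symbol_map = symbol_map, ortholog_map = ortholog_map,
              term_names = term_names)
  class(out) <- "pmd_catalog"
  out
}

#' Read a GMT-like term-set table
#'
#' Format: `term_id<TAB>term_name<TAB>id1<TAB>id2...`, one term per line.
#'
#' @param path File path.
#' @return Named list of member-id vectors, with a named character
#'   attribute `term_names`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); nm <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT format error at line ", i,
                             ": need term_id, term_name and >=1 member")
    sets[[f[[1]]]] <- unique(f[-c(1, 2)])
    nm[[f[[1]]]] <- f[[2]]
  }
  attr(sets, "term_names") <- nm
  sets
}

#' Read a publication metadata table (`pmid<TAB>interaction_count`)
#' @param path File path.
#' @return Data frame with columns `pmid` (character) and
#'   `interaction_count` (integer).
#' @export
read_publication_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = c("character", "integer"),
                         stringsAsFactors = FALSE)
  if (!all(c("pmid", "interaction_count") %in% names(d))) {
    stop("publication table must have columns pmid, interaction_count")
  }
  if (any(d$interaction_count < 0, na.rm = TRUE)) {
    stop("interaction_count must be non-negative")
  }
  d[, c("pmid", "interaction_count")]
}

#' Read an ortholog mapping table
#' @param path TSV with header `source_id source_organism target_id target_organism`.
#' @return Data frame with those four character columns.
#' @export
read_ortholog_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("source_id", "source_organism", "target_id", "target_organism")
  if (!all(need %in% names(d))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  }
  d[, need]
}

#' Read a single-column seed list
#' @param path TXT file, one identifier per line.
#' @return Character vector of tokens (blank lines dropped).
#' @export
read_seed_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x)]
}

#' Resolve identifier tokens against a catalog
#'
#' Accession-shaped tokens (recognizable metabolite/drug namespaces or
#' known store/catalog accessions) are matched directly.  Remaining tokens
#' are treated as gene symbols: reviewed (Swiss-Prot) candidates in the
#' organism are preferred, and only when no reviewed candidate exists is
#' the search extended to unreviewed (TrEMBL) candidates.  A symbol with
#' several candidates in the winning tier is reported as ambiguous, never
#' silently chosen.  Every input token lands in exactly one of the three
#' report sections.
#'
#' @param tokens Character vector of identifiers or symbols.
#' @param catalog A `pmd_catalog` with a `symbol_map`.
#' @param organism Taxon label restricting symbol lookups.
#' @param known_ids Optional character vector of accessions known to the
#'   store; tokens in this set resolve directly.
#' @return List with `resolved` (data frame `token`, `id`, `reviewed`),
#'   `ambiguous` (named list of candidate data frames) and `unresolved`
#'   (character vector).
#' @export
resolve_identifiers <- function(tokens, catalog, organism, known_ids = character()) {
  resolved <- data.frame(token = character(), id = character(),
                         reviewed = logical(), stringsAsFactors = FALSE)
  ambiguous <- list()
  unresolved <- character()
  sm <- catalog$symbol_map
  for (tok in tokens) {
    if (tok %in% known_ids || grepl("^(HMDB|YMDB|ECMDB|DB)[0-9]+$", tok)) {
      resolved <- rbind(resolved, data.frame(token = tok, id = tok,
                                             reviewed = NA, stringsAsFactors = FALSE))
      next
    }
    cand <- if (is.null(sm)) sm[0, ] else
      sm[sm$symbol == tok & sm$organism == organism, , drop = FALSE]
    if (is.null(cand) || nrow(cand) == 0L) {
      # fall back: accession-shaped protein token unknown to the catalog
      if (grepl("^[A-NR-Z][0-9][A-Z0-9]{3}[0-9]([A-Z0-9]{4})?$", tok)) {
        resolved <- rbind(resolved, data.frame(token = tok, id = tok,
                                               reviewed = NA, stringsAsFactors = FALSE))
      } else {
        unresolved <- c(unresolved, tok)
      }
      next
    }
    tier <- cand[cand$reviewed, , drop = FALSE]
    if (nrow(tier) == 0L) tier <- cand[!cand$reviewed, , drop = FALSE]
    if (nrow(tier) == 1L) {
      resolved <- rbind(resolved, data.frame(token = tok, id = tier$id,
                                             reviewed = tier$reviewed,
                                             stringsAsFactors = FALSE))
    } else {
      ambiguous[[tok]] <- tier
    }
  }
  list(resolved = resolved, ambiguous = ambiguous, unresolved = unresolved)
}

#' Map entities onto a target organism via an ortholog table
#'
#' Each mappable entity is replaced by its target-organism ortholog;
#' entities without a mapping are reported rather than silently dropped.
#' Many-to-one orthology collapses duplicates, with the multiplicity of
#' each target recorded.
#'
#' @param ids Character vector of accessions.
#' @param organism Source taxon label of the entities.
#' @param catalog A `pmd_catalog` with a non-empty `ortholog_map`.
#' @param target_organism Taxon label to map into.
#' @return List with `mapped` (data frame `target_id`, `multiplicity`),
#'   `unmapped` (character vector of source ids).
#' @export
map_orthologs <- function(ids, organism, catalog, target_organism) {
  om <- catalog$ortholog_map
  if (is.null(om) || nrow(om) == 0L) {
    stop("configuration error: empty ortholog map")
  }
  if (identical(organism, target_organism)) {
    return(list(mapped = data.frame(target_id = unique(ids),
                                    multiplicity = as.integer(table(ids)[unique(ids)]),
                                    stringsAsFactors = FALSE),
                unmapped = character()))
  }
  om <- om[om$source_organism == organism & om$target_organism == target_organism, ,
           drop = FALSE]
  hit <- match(ids, om$source_id)
  unmapped <- ids[is.na(hit)]
  targets <- om$target_id[hit[!is.na(hit)]]
  if (length(targets) == 0L) {
    return(list(mapped = data.frame(target_id = character(),
                                    multiplicity = integer(),
                                    stringsAsFactors = FALSE),
                unmapped = unmapped))
  }
  tab <- table(targets)
  list(mapped = data.frame(target_id = names(tab),
                           multiplicity = as.integer(tab),
                           stringsAsFactors = FALSE),
       unmapped = unmapped)
}

#' Collapse cellular-component annotations onto selected ancestor terms
#'
#' Each child term is replaced by its mapped main ancestor; ancestors
#' annotated (after mapping) for fewer than `min_genes` entities are
#' removed store-wide.  Child terms absent from the ancestor map are
#' retained as-is with a warning, then subjected to the same frequency
#' filter.
#'
#' @param raw_annotations Named list: entity id -> character vector of CC
#'   term ids.
#' @param ancestor_map Data frame with columns `child`, `ancestor`.
#' @param min_genes Minimum number of annotated entities for a term to be
#'   kept (default 10).
#' @return Named list: entity id -> character vector of selected ancestor
#'   terms (entities losing all terms keep an empty vector).
#' @export
select_cc_terms <- function(raw_annotations, ancestor_map, min_genes = 10L) {
  stopifnot(is.list(raw_annotations))
  unknown <- character()
  mapped <- lapply(raw_annotations, function(terms) {
    hit <- match(terms, ancestor_map$child)
    out <- ifelse(is.na(hit), terms, ancestor_map$ancestor[hit])
    unknown <<- c(unknown, terms[is.na(hit)])
    unique(out)
  })
  if (length(unknown) > 0L) {
    warning("CC term(s) absent from ancestor map retained as-is: ",
            paste(sort(unique(unknown)), collapse = ", "))
  }
  counts <- table(unlist(lapply(mapped, unique)))
  keep <- names(counts)[counts >= min_genes]
  lapply(mapped, function(terms) terms[terms %in% keep])
}
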