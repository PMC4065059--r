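# Interaction store: parse, unify, deduplicate and index heterogeneous
# interaction evidence (proteins, metabolites, drugs) into a queryable
# local store keyed by canonical pair identifiers.

#' Infer the entity kind of an accession
#'
#' Kind is decided by identifier namespace: HMDB/YMDB/ECMDB-style ids are
#' metabolites, DrugBank-style ids (`DB` followed by digits) are drugs,
#' anything else is treated as a protein accession.
#'
#' @param id Character vector of accession strings.
#' @return Character vector with values `"protein"`, `"metabolite"` or
#'   `"drug"`.
#' @export
#' @examples
#' entity_kind(c("P12345", "HMDB0000122", "DB00316"))
entity_kind <- function(id) {
  kind <- rep("protein", length(id))
  kind[grepl("^(HMDB|YMDB|ECMDB)[0-9]+$", id)] <- "metabolite"
  kind[grepl("^DB[0-9]+$", id)] <- "drug"
  kind
}

.empty_records <- function() {
  data.frame(
    id_a = character(), id_b = character(),
    kind_a = character(), kind_b = character(),
    organism_a = character(), organism_b = character(),
    evidence = character(), method = character(),
    pmid = character(), source_db = character(),
    stringsAsFactors = FALSE
  )
}

#' Read an interaction table
#'
#' Two dialects are supported.  The native dialect is a UTF-8 TSV with
#' header `id_a id_b organism_a organism_b evidence method pmid source_db`
#' and `.` for missing optional fields.  The PSI-MI TAB 2.5 dialect reads a
#' minimal column subset: interactor ids (columns 1-2), interaction
#' detection method (7), publication id (9), taxids (10-11) and source
#' database (13); PSI-MI rows carry experimental evidence by construction.
#'
#' @param path Path to the file.
#' @param dialect `"native_tsv"` or `"psimitab25"`.
#' @return A data frame of interaction records, one row per input data row,
#'   with columns `id_a`, `id_b`, `kind_a`, `kind_b`, `organism_a`,
#'   `organism_b`, `evidence`, `method`, `pmid`, `source_db`.  Missing
#'   optional fields are `""`.
#' @export
read_interaction_table <- function(path, dialect = c("native_tsv", "psimitab25")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interaction table not found: ", path)
  if (dialect == "native_tsv") .read_native_tsv(path) else .read_psimitab25(path)
}

.read_native_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty interaction table: ", path)
    return(.empty_records())
  }
  required <- c("id_a", "id_b", "organism_a", "organism_b",
                "evidence", "method", "pmid", "source_db")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop("interaction table format error: missing mandatory column(s) ",
         paste(missing, collapse = ", "))
  }
  if (length(lines) == 1L) {
    warning("interaction table has a header but no data rows: ", path)
    return(.empty_records())
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  idx <- match(required, header)
  rows <- lapply(seq_along(cells), function(i) {
    row <- cells[[i]]
    if (length(row) < max(idx)) {
      stop("interaction table format error at data row ", i,
           ": expected at least ", max(idx), " columns, found ", length(row))
    }
    row[idx]
  })
  m <- do.call(rbind, rows)
  m[m == "."] <- ""
  ev <- m[, 5]
  bad <- which(!ev %in% c("experimental", "predicted"))
  if (length(bad) > 0L) {
    stop("interaction table format error at data row ", bad[[1]],
         ": evidence must be 'experimental' or 'predicted', found '",
         ev[bad[[1]]], "'")
  }
  data.frame(
    id_a = m[, 1], id_b = m[, 2],
    kind_a = entity_kind(m[, 1]), kind_b = entity_kind(m[, 2]),
    organism_a = m[, 3], organism_b = m[, 4],
    evidence = ev, method = m[, 6], pmid = m[, 7], source_db = m[, 8],
    stringsAsFactors = FALSE
  )
}

# Strip a "namespace:" prefix and any trailing "(description)" from a
# PSI-MI TAB field, e.g. 'uniprotkb:P12345' or 'taxid:9606(human)'.
.psimi_value <- function(x) {
  x <- sub("\\(.*\\)$", "", x)
  sub("^[^:]*:", "", x)
}

.read_psimitab25 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty interaction table: ", path)
    return(.empty_records())
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(cells), function(i) {
    row <- cells[[i]]
    if (length(row) < 13L) {
      stop("PSI-MI TAB format error at row ", i,
           ": expected at least 13 columns, found ", length(row))
    }
    id_a <- .psimi_value(row[[1]])
    id_b <- .psimi_value(row[[2]])
    pmid <- .psimi_value(row[[9]])
    if (pmid == "-") pmid <- ""
    method <- row[[7]]
    mdesc <- regmatches(method, regexpr("\\(([^)]*)\\)", method))
    method <- if (length(mdesc) == 1L) substr(mdesc, 2L, nchar(mdesc) - 1L) else .psimi_value(method)
    src <- row[[13]]
    sdesc <- regmatches(src, regexpr("\\(([^)]*)\\)", src))
    src <- if (length(sdesc) == 1L) substr(sdesc, 2L, nchar(sdesc) - 1L) else .psimi_value(src)
    c(id_a, id_b, .psimi_value(row[[10]]), .psimi_value(row[[11]]), method, pmid, src)
  })
  m <- do.call(rbind, rows)
  m[m == "-"] <- ""
  data.frame(
    id_a = m[, 1], id_b = m[, 2],
    kind_a = entity_kind(m[, 1]), kind_b = entity_kind(m[, 2]),
    organism_a = m[, 3], organism_b = m[, 4],
    evidence = "experimental", method = m[, 5], pmid = m[, 6],
    source_db = m[, 7], stringsAsFactors = FALSE
  )
}

#' Canonical pair key of an interaction record
#'
#' The key concatenates the two accessions in lexicographic order with the
#' publication id (`idA_idB_pmid`); records lacking a publication get an
#' empty-pmid sentinel so that unpublished evidence for the same pair still
#' collapses onto one row.  The key is invariant under swapping the two
#' interactors.
#'
#' @param id_a,id_b Accession strings (vectorized).
#' @param pmid Publication ids; `""` or `NA` for unpublished records.
#' @return Character vector of keys.
#' @export
canonical_pair_key <- function(id_a, id_b, pmid = "") {
  pmid[is.na(pmid)] <- ""
  first <- ifelse(id_a <= id_b, id_a, id_b)
  second <- ifelse(id_a <= id_b, id_b, id_a)
  paste(first, second, pmid, sep = "_")
}

#' Canonical unordered pair id (no publication component)
#' @inheritParams canonical_pair_key
#' @return Character vector `idA_idB` with ids in lexicographic order.
#' @export
pair_id <- function(id_a, id_b) {
  first <- ifelse(id_a <= id_b, id_a, id_b)
  second <- ifelse(id_a <= id_b, id_b, id_a)
  paste(first, second, sep = "_")
}

.join_uniq <- function(x) {
  x <- unique(x[nzchar(x)])
  paste(sort(x), collapse = ";")
}

#' Deduplicate interaction records into a pair-level store
#'
#' Evidence rows are first collapsed per canonical (pair, pmid) key, merging
#' source databases and methods of redundant reports; keys then collapse at
#' the unordered-pair level, accumulating the publication set of each pair.
#' A pair is experimental if any contributing record is experimental.
#'
#' @param records Data frame as returned by [read_interaction_table()]
#'   (several tables may be `rbind`ed first).
#' @param publications Optional data frame with columns `pmid` and
#'   `interaction_count` (see [read_publication_table()]).
#' @return A `pmd_store` object; see [pmd_store()].
#' @export
deduplicate <- function(records, publications = NULL) {
  pmd_store(records, publications)
}

#' Build a deduplicated interaction store
#'
#' @inheritParams deduplicate
#' @param catalog Optional annotation catalog (see [annotation_catalog()]).
#' @return An object of class `pmd_store` with elements:
#'   \describe{
#'     \item{evidence}{one row per canonical (pair, pmid) key with merged
#'       `sources` and `methods`.}
#'     \item{pairs}{one row per unordered pair: ids, kinds, organisms,
#'       `evidence` (`"experimental"` if any row is), `pmids`, `methods`,
#'       `sources` (all `;`-joined), `n_pubs`, `self` flag.}
#'     \item{entities}{one row per distinct (id, organism).}
#'     \item{publications}{pmid to interaction-count table.}
#'     \item{catalog}{annotation catalog or `NULL`.}
#'   }
#' @export
pmd_store <- function(records, publications = NULL, catalog = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    ev <- data.frame(key = character(), pair = character(), id_a = character(),
                     id_b = character(), pmid = character(), evidence = character(),
                     methods = character(), sources = character(),
                     stringsAsFactors = FALSE)
    pairs <- data.frame(pair = character(), id_a = character(), id_b = character(),
                        kind_a = character(), kind_b = character(),
                        organism_a = character(), organism_b = character(),
                        evidence = character(), pmids = character(),
                        methods = character(), sources = character(),
                        n_pubs = integer(), self = logical(),
                        stringsAsFactors = FALSE)
    entities <- data.frame(id = character(), kind = character(),
                           organism = character(), stringsAsFactors = FALSE)
    out <- list(evidence = ev, pairs = pairs, entities = entities,
                publications = publications, catalog = catalog)
    class(out) <- "pmd_store"
    return(out)
  }
  # canonical orientation of every record
  swap <- records$id_a > records$id_b
  rec <- records
  rec[swap, c("id_a", "id_b", "kind_a", "kind_b", "organism_a", "organism_b")] <-
    records[swap, c("id_b", "id_a", "kind_b", "kind_a", "organism_b", "organism_a")]
  rec$pmid[is.na(rec$pmid)] <- ""
  rec$key <- canonical_pair_key(rec$id_a, rec$id_b, rec$pmid)
  rec$pair <- pair_id(rec$id_a, rec$id_b)

  # evidence level: one row per (pair, pmid) key
  ev_split <- split(rec, rec$key)
  ev <- do.call(rbind, lapply(ev_split, function(d) {
    data.frame(key = d$key[[1]], pair = d$pair[[1]],
               id_a = d$id_a[[1]], id_b = d$id_b[[1]], pmid = d$pmid[[1]],
               evidence = if (any(d$evidence == "experimental")) "experimental" else "predicted",
               methods = .join_uniq(d$method), sources = .join_uniq(d$source_db),
               stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$key), , drop = FALSE]
  rownames(ev) <- NULL

  # pair level: accumulate publications across keys
  pr_split <- split(rec, rec$pair)
  pairs <- do.call(rbind, lapply(pr_split, function(d) {
    data.frame(pair = d$pair[[1]], id_a = d$id_a[[1]], id_b = d$id_b[[1]],
               kind_a = d$kind_a[[1]], kind_b = d$kind_b[[1]],
               organism_a = d$organism_a[[1]], organism_b = d$organism_b[[1]],
               evidence = if (any(d$evidence == "experimental")) "experimental" else "predicted",
               pmids = .join_uniq(d$pmid), methods = .join_uniq(d$method),
               sources = .join_uniq(d$source_db),
               n_pubs = length(unique(d$pmid[nzchar(d$pmid)])),
               self = d$id_a[[1]] == d$id_b[[1]],
               stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(pairs$pair), , drop = FALSE]
  rownames(pairs) <- NULL

  ents <- unique(data.frame(
    id = c(rec$id_a, rec$id_b),
    kind = c(rec$kind_a, rec$kind_b),
    organism = c(rec$organism_a, rec$organism_b),
    stringsAsFactors = FALSE
  ))
  ents <- ents[order(ents$id, ents$organism), , drop = FALSE]
  rownames(ents) <- NULL

  out <- list(evidence = ev, pairs = pairs, entities = ents,
              publications = publications, catalog = catalog)
  class(out) <- "pmd_store"
  out
}

#' @export
print.pmd_store <- function(x, ...) {
  cat("pmd_store:", nrow(x$pairs), "unique pairs,",
      nrow(x$evidence), "evidence rows,", nrow(x$entities), "entities\n")
  invisible(x)
}

#' Interaction partners of an entity
#'
#' Distinct partners over unique pairs; self-interactions are excluded, and
#' metabolite or drug partners are returned only when the corresponding
#' flag is on.  An entity absent from the store has no partners.
#'
#' @param store A `pmd_store`.
#' @param id Accession of the query entity.
#' @param include_metabolites,include_drugs Include partners of that kind.
#' @return Character vector of partner accessions (sorted).
#' @export
store_neighbors <- function(store, id, include_metabolites = FALSE,
                            include_drugs = FALSE) {
  p <- store$pairs
  hit_a <- p$id_a == id & !p$self
  hit_b <- p$id_b == id & !p$self
  partners <- c(p$id_b[hit_a], p$id_a[hit_b])
  kinds <- c(p$kind_b[hit_a], p$kind_a[hit_b])
  keep <- kinds == "protein" |
    (kinds == "metabolite" & include_metabolites) |
    (kinds == "drug" & include_drugs)
  sort(unique(partners[keep]))
}

#' Restrict a store to pairs involving a given organism
#'
#' A pair is retained when either interactor carries the organism label
#' (records may span two organisms, e.g. host-pathogen pairs).
#'
#' @param store A `pmd_store`.
#' @param organism Taxon label.
#' @return A filtered `pmd_store` sharing the catalog and publications.
#' @export
store_filter_organism <- function(store, organism) {
  keep <- store$pairs$organism_a == organism | store$pairs$organism_b == organism
  out <- store
  out$pairs <- store$pairs[keep, , drop = FALSE]
  out$evidence <- store$evidence[store$evidence$pair %in% out$pairs$pair, , drop = FALSE]
  ids <- unique(c(out$pairs$id_a, out$pairs$id_b))
  out$entities <- store$entities[store$entities$id %in% ids, , drop = FALSE]
  out
}
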