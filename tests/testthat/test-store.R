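# interaction store: parsing, canonical keys, deduplication, neighbors,
# identifier resolution, orthologs, CC term selection

test_that("native TSV reader maps fields and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "id_a\tid_b\torganism_a\torganism_b\tevidence\tmethod\tpmid\tsource_db",
    "P1\tP2\torgA\torgA\texperimental\ttwo hybrid\t11\tBioGRID",
    "P2\tHMDB0000001\torgA\torgA\tpredicted\t.\t.\tHMDB"
  ), path)
  rec <- read_interaction_table(path, "native_tsv")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$id_a, c("P1", "P2"))
  expect_equal(rec$kind_b, c("protein", "metabolite"))
  expect_equal(rec$pmid, c("11", ""))    # '.' means missing
  expect_equal(rec$method[2], "")

  # enum violation is reported with its row number
  writeLines(c(
    "id_a\tid_b\torganism_a\torganism_b\tevidence\tmethod\tpmid\tsource_db",
    "P1\tP2\torgA\torgA\texperimental\tm\t1\tdb",
    "P3\tP4\torgA\torgA\texp?\tm\t1\tdb"
  ), path)
  expect_error(read_interaction_table(path, "native_tsv"), "row 2.*exp\\?")

  # missing mandatory column is named
  writeLines(c("id_a\tid_b\torganism_a\torganism_b\tmethod\tpmid\tsource_db",
               "P1\tP2\torgA\torgA\tm\t1\tdb"), path)
  expect_error(read_interaction_table(path, "native_tsv"), "evidence")

  writeLines(character(), path)
  expect_warning(rec0 <- read_interaction_table(path, "native_tsv"), "empty")
  expect_equal(nrow(rec0), 0L)
})

test_that("PSI-MI TAB 2.5 line matches its hand-parsed reference", {
  # hand-parsed reference for the line below: ids P12345/Q67890 (strip the
  # 'uniprotkb:' namespace), method 'two hybrid' (parenthesized label),
  # pmid 11111, taxids 9606/9606, source db 'intact'
  line <- paste("uniprotkb:P12345", "uniprotkb:Q67890", "-", "-", "-",
                "-", "psi-mi:\"MI:0018\"(two hybrid)", "-", "pubmed:11111",
                "taxid:9606(human)", "taxid:9606(human)", "-",
                "psi-mi:\"MI:0469\"(intact)", "-", "-", sep = "\t")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(line, path)
  rec <- read_interaction_table(path, "psimitab25")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id_a, "P12345")
  expect_equal(rec$id_b, "Q67890")
  expect_equal(rec$method, "two hybrid")
  expect_equal(rec$pmid, "11111")
  expect_equal(rec$organism_a, "9606")
  expect_equal(rec$organism_b, "9606")
  expect_equal(rec$source_db, "intact")
  expect_equal(rec$evidence, "experimental")
})

test_that("canonical pair keys are order-insensitive and pmid-aware", {
  expect_identical(canonical_pair_key("Q9Z999", "A0A001", "123"),
                   canonical_pair_key("A0A001", "Q9Z999", "123"))
  k_nopmid <- canonical_pair_key("P1", "P2", "")
  expect_false(identical(k_nopmid, canonical_pair_key("P1", "P2", "5")))
  expect_identical(k_nopmid, canonical_pair_key("P2", "P1", NA))
  # 4 records forming 2 symmetric duplicates -> 2 distinct keys
  keys <- canonical_pair_key(c("A", "B", "A", "C"), c("B", "A", "C", "A"),
                             c("1", "1", "1", "1"))
  expect_equal(length(unique(keys)), 2L)
})

test_that("deduplication merges sources and accumulates publications", {
  # same pair + pmid from two databases -> 1 evidence row, merged sources
  rec <- rbind(make_records("P1", "P2", pmid = "11", source_db = "BioGRID"),
               make_records("P2", "P1", pmid = "11", source_db = "IntAct"))
  st <- deduplicate(rec)
  expect_equal(nrow(st$evidence), 1L)
  expect_equal(st$evidence$sources, "BioGRID;IntAct")

  # same pair with pmids 1 and 2 -> one pair with publication set {1,2}
  rec2 <- rbind(make_records("P1", "P2", pmid = "1"),
                make_records("P1", "P2", pmid = "2"))
  st2 <- deduplicate(rec2)
  expect_equal(nrow(st2$evidence), 2L)
  expect_equal(nrow(st2$pairs), 1L)
  expect_equal(st2$pairs$pmids, "1;2")
  expect_equal(st2$pairs$n_pubs, 2L)
})

test_that("deduplication is idempotent and order-insensitive", {
  set.seed(42)
  ids <- paste0("P", 1:8)
  rec <- make_records(sample(ids, 40, TRUE), sample(ids, 40, TRUE),
                      evidence = sample(c("experimental", "predicted"), 40, TRUE),
                      pmid = sample(c("", "1", "2", "3"), 40, TRUE),
                      source_db = sample(c("A", "B"), 40, TRUE))
  st <- pmd_store(rec)
  expect_lte(nrow(st$pairs), nrow(rec))
  # shuffling the input record order yields an identical store
  for (i in 1:3) {
    st2 <- pmd_store(rec[sample(nrow(rec)), ])
    expect_identical(st$pairs, st2$pairs)
    expect_identical(st$evidence, st2$evidence)
  }
  # dedup of the store's own evidence rows changes nothing
  ev <- st$evidence
  rec3 <- make_records(ev$id_a, ev$id_b, pmid = ev$pmid)
  expect_equal(nrow(pmd_store(rec3)$evidence), nrow(ev))
})

test_that("neighbors honour kind flags, dedup and self-exclusion", {
  st <- tiny_store()
  expect_equal(store_neighbors(st, "P2"), c("P1", "P3"))
  expect_equal(store_neighbors(st, "P2", include_metabolites = TRUE),
               c("HMDB0000001", "P1", "P3"))
  expect_equal(store_neighbors(st, "P2", TRUE, TRUE),
               c("DB00001", "HMDB0000001", "P1", "P3"))
  # P1-P2 backed by 3 evidence rows still counts once
  expect_equal(store_neighbors(st, "P1"), "P2")
  # absent entity -> empty set, not an error
  expect_equal(store_neighbors(st, "NOPE"), character())
  # self-interactions never appear as neighbors
  st_self <- pmd_store(make_records(c("P1", "P1"), c("P1", "P2")))
  expect_equal(store_neighbors(st_self, "P1"), "P2")
})

test_that("identifier resolution prefers reviewed and partitions tokens", {
  sm <- data.frame(
    symbol = c("GSY1", "GSY1", "ALB", "DUP", "DUP"),
    id = c("P10001", "Q99999", "P02768", "P11111", "P22222"),
    reviewed = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    organism = "orgA", stringsAsFactors = FALSE)
  cat <- annotation_catalog(symbol_map = sm)
  tokens <- c("GSY1", "ALB", "DUP", "XYZ_NOT_A_GENE", "P12345", "HMDB0000001")
  res <- resolve_identifiers(tokens, cat, "orgA", known_ids = "P12345")
  # reviewed beats unreviewed
  expect_equal(res$resolved$id[res$resolved$token == "GSY1"], "P10001")
  # unreviewed-only symbol still resolves
  expect_equal(res$resolved$id[res$resolved$token == "ALB"], "P02768")
  # two reviewed candidates -> ambiguous with all candidates listed
  expect_named(res$ambiguous, "DUP")
  expect_setequal(res$ambiguous$DUP$id, c("P11111", "P22222"))
  expect_equal(res$unresolved, "XYZ_NOT_A_GENE")
  # every token appears exactly once across the three sections
  expect_equal(nrow(res$resolved) + length(res$ambiguous) + length(res$unresolved),
               length(tokens))
})

test_that("ortholog mapping reports unmapped entities and multiplicity", {
  om <- data.frame(source_id = c("P1", "P2", "P3"), source_organism = "orgA",
                   target_id = c("Q1", "Q2", "Q1"), target_organism = "orgB",
                   stringsAsFactors = FALSE)
  cat <- annotation_catalog(ortholog_map = om)
  # identity: target organism equals source
  idm <- map_orthologs(c("P1", "P9"), "orgA", cat, "orgA")
  expect_setequal(idm$mapped$target_id, c("P1", "P9"))
  # 3 entities, 2 in map -> 2 mapped + 1 unmapped
  r <- map_orthologs(c("P1", "P2", "P9"), "orgA", cat, "orgB")
  expect_setequal(r$mapped$target_id, c("Q1", "Q2"))
  expect_equal(r$unmapped, "P9")
  # many-to-one collapses with multiplicity (hand-applied: P1,P3 -> Q1 x2)
  r2 <- map_orthologs(c("P1", "P2", "P3"), "orgA", cat, "orgB")
  expect_equal(r2$mapped$multiplicity[r2$mapped$target_id == "Q1"], 2L)
  expect_error(map_orthologs("P1", "orgA", annotation_catalog(), "orgB"),
               "configuration error")
})

test_that("CC selection maps to ancestors and applies the >=10 filter", {
  amap <- data.frame(child = paste0("c", 1:4),
                     ancestor = c("nucleus", "nucleus", "nucleus", "golgi"),
                     stringsAsFactors = FALSE)
  # 12 entities annotated to children of nucleus, 9 to golgi
  raw <- c(lapply(1:12, function(i) sample(c("c1", "c2", "c3"), 1)),
           lapply(1:9, function(i) "c4"))
  names(raw) <- paste0("E", 1:21)
  sel <- select_cc_terms(raw, amap, min_genes = 10L)
  expect_true(all(vapply(sel[1:12], function(x) "nucleus" %in% x, logical(1))))
  # golgi annotated for 9 < 10 entities is dropped everywhere
  expect_false(any(vapply(sel, function(x) "golgi" %in% x, logical(1))))
  # min_genes = 1: nothing dropped
  sel1 <- select_cc_terms(raw, amap, min_genes = 1L)
  expect_true(any(vapply(sel1, function(x) "golgi" %in% x, logical(1))))
  # unknown child retained as-is, with warning, then counted like any term
  expect_warning(sel2 <- select_cc_terms(list(E1 = "weird"), amap, 1L), "weird")
  expect_equal(sel2$E1, "weird")
  # output never contains a term under the frequency threshold
  counts <- table(unlist(sel))
  expect_true(all(counts >= 10))
})

test_that("organism filtering keeps pairs touching the organism", {
  rec <- rbind(make_records("P1", "P2", organism = "orgA"),
               make_records("P3", "P4", organism = "orgB"))
  rec$organism_b[1] <- "orgB"   # host-pathogen style pair
  st <- pmd_store(rec)
  stA <- store_filter_organism(st, "orgA")
  expect_equal(stA$pairs$pair, "P1_P2")
  stB <- store_filter_organism(st, "orgB")
  expect_setequal(stB$pairs$pair, c("P1_P2", "P3_P4"))
})
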