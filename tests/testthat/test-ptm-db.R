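test_that("database inclusion follows the KW/FT annotation rules", {
  vocab <- test_vocab()
  recs <- list(
    make_record("KWONLY_TEST", "P00001", keywords = "Phosphoprotein"),
    make_record("FTONLY_TEST", "P00002", features = mod_res("Phosphoserine")),
    # CARBOHYD is outside the default ft_keys and "Transport" is no PTM keyword
    make_record("NONPTM_TEST", "P00003", keywords = "Transport",
                features = mod_res("N-linked glycosylation", key = "CARBOHYD")),
    make_record("UNREV_TEST", "P00004", keywords = "Phosphoprotein",
                review_status = "Unreviewed"),
    make_record("BOTH_TEST", "P00005", keywords = "glycoprotein",
                features = mod_res("Phosphoserine (By similarity)"))
  )
  db <- build_database(recs, vocab)
  expect_setequal(db$proteins$accession, c("P00001", "P00002", "P00005"))
  tags <- setNames(db$proteins$source_tag, db$proteins$accession)
  expect_identical(tags[["P00001"]], "KW-only")
  expect_identical(tags[["P00002"]], "FT-only")
  expect_identical(tags[["P00005"]], "Both")  # keyword match is case-insensitive
  v <- annotation_source_partition(db)
  expect_identical(v$total, v$kw_only + v$ft_only + v$both)
})

test_that("unmatched normalized FT terms survive as ad-hoc uncategorized terms", {
  db <- build_database(
    list(make_record("ADHOC_TEST", "P00010",
                     features = mod_res("3-oxoalanine (Probable)"))),
    test_vocab()
  )
  expect_identical(nrow(db$proteins), 1L)
  expect_true("ft-3-oxoalanine" %in% db$terms$term_id)
  expect_true("uncategorized" %in% db$terms$term_id)
  expect_identical(db$evidence$qualifier, "Putative")
})

test_that("Venn counts and percentages follow the printed-count conventions", {
  expect_error(venn_counts(-1, 0, 0), class = "ptmenrich_param_error")
  v <- venn_counts(6, 1, 3)
  expect_identical(v$total, 10)
  empty <- venn_counts(0, 0, 0)
  expect_identical(unname(venn_percent(empty)), c(0, 0, 0))
  # the published curation: 129553 + 4740 + 82104 proteins partition into
  # 60% / 2% / 38% at nearest-integer rounding
  pub <- venn_counts(129553, 4740, 82104)
  expect_identical(pub$total, 216397)
  expect_identical(venn_percent(pub),
                   c(kw_only = 60, ft_only = 2, both = 38))
})

test_that("feature-key composition counts once per key per protein", {
  vocab <- test_vocab()
  recs <- list(
    make_record("A_TEST", "P00001",
                features = rbind(mod_res("Phosphoserine"),
                                 mod_res("Phosphothreonine", begin = 20L),
                                 mod_res("S-palmitoyl cysteine", key = "LIPID"))),
    make_record("B_TEST", "P00002", features = mod_res("Phosphoserine"))
  )
  db <- build_database(recs, vocab)
  comp <- ft_key_composition(db)
  counts <- setNames(comp$count, comp$key)
  # P00001 has two MOD_RES features but counts once for the key
  expect_identical(counts[["MOD_RES"]], 2L)
  expect_identical(counts[["LIPID"]], 1L)
  expect_identical(counts[["CROSSLNK"]], 0L)
  expect_identical(setNames(comp$percent, comp$key)[["MOD_RES"]],
                   round(100 * 2 / 3, 2))
  # composition percentages: 2-decimal rounding of count / sum(counts)
  expect_equal(unname(composition_percent(c(62675, 8681, 4091))),
               c(83.07, 11.51, 5.42))
  expect_identical(unname(composition_percent(c(0, 0))), c(0, 0))
  expect_identical(unname(composition_percent(c(5, 0))), c(100, 0))
})

test_that("term frequencies match an independent brute-force recount", {
  set.seed(21)
  recs <- lapply(1:120, random_record)
  vocab <- default_vocabulary()
  db <- build_database(recs, vocab)
  freq <- term_frequencies(db)
  # oracle: scan raw records, applying the inclusion rules independently
  oracle <- new.env()
  for (r in recs) {
    if (r$review_status != "Reviewed") next
    kw <- vocab$kw$term_id[match(tolower(r$keywords), tolower(vocab$kw$label))]
    kw <- kw[!is.na(kw)]
    f <- r$features[r$features$key %in% c("MOD_RES", "LIPID", "CROSSLNK"), ]
    labs <- normalize_ft_description(f$description)$label
    labs <- labs[!is.na(labs)]
    ft <- vocab$ft$term_id[match(tolower(labs), tolower(vocab$ft$label))]
    ft[is.na(ft)] <- paste0("ft-", gsub("[^a-z0-9]+", "-", tolower(labs[is.na(ft)])))
    for (t in unique(c(kw, ft))) {
      oracle[[t]] <- (if (is.null(oracle[[t]])) 0L else oracle[[t]]) + 1L
    }
  }
  expect_identical(nrow(freq), length(ls(oracle)))
  for (i in seq_len(nrow(freq))) {
    expect_identical(freq$count[i], oracle[[freq$term_id[i]]])
  }
  # descending by count, ties by label
  expect_true(all(diff(freq$count) <= 0))
  # single-organism database: ALL equals the organism-specific view
  one_org <- build_database(recs[vapply(recs, function(r)
    r$organism_key == "Homo sapiens", logical(1))], vocab)
  expect_identical(term_frequencies(one_org, "ALL"),
                   term_frequencies(one_org, "Homo sapiens"))
  expect_error(term_frequencies(db, "Homo sapien"), "nearest",
               class = "ptmenrich_db_error")
})

test_that("evidence dictionaries split by qualifier and merge into totals", {
  vocab <- test_vocab()
  recs <- c(
    lapply(1:3, function(i) make_record(sprintf("EXP%d_TEST", i),
                                        sprintf("P1000%d", i),
                                        features = mod_res("Phosphoserine"))),
    list(make_record("PUT1_TEST", "P20001",
                     features = mod_res("Phosphoserine (By similarity)")))
  )
  db <- build_database(recs, vocab)
  dict <- evidence_dictionaries(db)
  expect_identical(dict$experimental$count, 3L)
  expect_identical(dict$putative$count, 1L)
  expect_identical(dict$total$count, 4L)
  empty <- build_database(list(make_record("KW1_TEST", "P30001",
                                           keywords = "Phosphoprotein")), vocab)
  d0 <- evidence_dictionaries(empty)
  expect_identical(nrow(d0$experimental) + nrow(d0$putative) + nrow(d0$total), 0L)
})

test_that("identifier resolution is case-insensitive, deduplicating and organism-scoped", {
  vocab <- test_vocab()
  recs <- list(
    make_record("HUM1_HUMAN", c("P12345", "Q00001"), organism = "Homo sapiens (Human)",
                keywords = "Phosphoprotein"),
    make_record("MOU1_MOUSE", "P54321", organism = "Mus musculus (Mouse)",
                keywords = "Phosphoprotein")
  )
  db <- build_database(recs, vocab)
  r <- resolve_proteins(db, "Homo sapiens",
                        c("p12345", "P12345", "q00001", "hum1_human", "P54321", ""))
  expect_identical(r$matched, "P12345")
  expect_identical(r$unmatched, "P54321")
  expect_error(resolve_proteins(db, "Homo sapiens", "P54321"),
               "organism", class = "ptmenrich_resolve_error")
  expect_error(resolve_proteins(db, "Homo sapiens", c("", "# comment")),
               class = "ptmenrich_resolve_error")
})

test_that("database building is order-independent and archives round-trip", {
  set.seed(22)
  recs <- lapply(1:80, random_record)
  vocab <- default_vocabulary()
  db1 <- build_database(recs, vocab)
  db2 <- build_database(rev(recs), vocab)
  expect_identical(db1, db2)
  dir <- tempfile()
  write_database(db1, dir)
  db3 <- read_database(dir)
  expect_identical(db3$proteins$accession, db1$proteins$accession)
  expect_identical(db3$term_index, db1$term_index)
  expect_identical(db3$fingerprint, db1$fingerprint)
  expect_identical(db3$params$ft_keys, db1$params$ft_keys)
  # bit-stable archive across rebuilds
  dir2 <- tempfile()
  write_database(db2, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})
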