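# deterministic database: one organism, 20 proteins; term A (Phosphoserine)
# on exactly 5 proteins, a universal keyword on all 20
analysis_db <- function() {
  recs <- lapply(1:20, function(i) {
    feats <- if (i <= 5) mod_res("Phosphoserine") else ptmenrich:::empty_features()
    dr <- if (i == 1L) {
      data.frame(database = c("PhosphoSite", "UniCarbKB"),
                 id = c("X1", "X2"), stringsAsFactors = FALSE)
    } else NULL
    make_record(sprintf("EN%02d_TEST", i), sprintf("P000%02d", i),
                keywords = "Phosphoprotein", features = feats, cross_refs = dr)
  })
  build_database(recs, test_vocab())
}

test_that("enrichment reproduces the closed-form tail for a fully recovered term", {
  db <- analysis_db()
  res <- enrich(db, "Testus organismus", sprintf("P000%02d", 1:5),
                correction = "none")
  row <- res$rows[res$rows$term_id == "ft-phosphoserine", ]
  expect_identical(row$freq_db, 5L)
  expect_identical(row$freq_list, 5L)
  expect_identical(res$context$n, 5L)
  expect_identical(res$context$N, 20L)
  expect_equal(row$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row$p_value, enum_tail_prob(20, 5, 5, 5), tolerance = 1e-12)
  # the universal keyword has K = N, forcing p = 1
  kw <- res$rows[res$rows$term_id == "phosphoprotein", ]
  expect_identical(kw$freq_db, 20L)
  expect_identical(kw$p_value, 1)
})

test_that("querying the full background gives m = K and p = 1 for every term", {
  db <- analysis_db()
  res <- enrich(db, "Testus organismus", db$proteins$accession,
                correction = "none")
  expect_identical(res$all_terms$freq_list, res$all_terms$freq_db)
  expect_true(all(res$all_terms$p_value == 1))
  expect_identical(res$context$n, res$context$N)
})

test_that("correction and alpha drive the significance decision", {
  db <- analysis_db()
  ids <- sprintf("P000%02d", 1:5)
  bon <- enrich(db, "Testus organismus", ids, correction = "bonferroni")
  expect_equal(bon$context$adjusted_alpha, 0.05 / bon$context$n_tests)
  row <- bon$rows[bon$rows$term_id == "ft-phosphoserine", ]
  expect_equal(row$adjusted_p, min(1, row$p_value * bon$context$n_tests))
  expect_true(row$significant)
  none <- enrich(db, "Testus organismus", ids, correction = "none")
  expect_true(all(is.na(none$rows$adjusted_p)))
  expect_error(enrich(db, "Testus organismus", ids, alpha = 1.2),
               class = "ptmenrich_param_error")
})

test_that("rows with no list hits are excluded from enrichment but kept in frequency", {
  db <- analysis_db()
  ids <- sprintf("P000%02d", 6:8)  # no Phosphoserine carriers
  res <- enrich(db, "Testus organismus", ids, correction = "none")
  expect_false("ft-phosphoserine" %in% res$rows$term_id)
  expect_true("ft-phosphoserine" %in% res$all_terms$term_id)
  fr <- list_frequency(db, "Testus organismus", ids)
  frow <- fr$rows[fr$rows$term_id == "ft-phosphoserine", ]
  expect_identical(frow$freq_list, 0L)
  expect_identical(frow$freq_db, 5L)
})

test_that("a list equal to the whole partition reproduces the organism percentages", {
  db <- analysis_db()
  fr <- list_frequency(db, "Testus organismus", db$proteins$accession)
  expect_equal(fr$rows$pct_list, fr$rows$pct_db)
})

test_that("cross-reference markers map DR names to the numeric labels", {
  rec <- make_record("XR_TEST", "P11111",
                     cross_refs = data.frame(database = "PhosphoSite", id = "x"))
  expect_identical(crossref_markers(rec), 2L)
  expect_identical(crossref_markers(make_record("XR2_TEST", "P11112")), integer())
  both <- make_record("XR3_TEST", "P11113",
                      cross_refs = data.frame(database = c("PhosphoSitePlus",
                                                           "UniCarbKB"),
                                              id = c("x", "y")))
  expect_identical(crossref_markers(both), c(2L, 3L))
  expect_identical(ptmenrich:::render_markers(c(2L, 3L)), "(2)(3)")
  # markers surface next to the accession in result tables
  db <- analysis_db()
  res <- enrich(db, "Testus organismus", "P00001", correction = "none")
  row <- res$rows[res$rows$term_id == "ft-phosphoserine", ]
  expect_match(row$members, "P00001(2)(3)", fixed = TRUE)
})

test_that("matching takes the union of significant terms with per-list provenance", {
  db <- analysis_db()
  ids1 <- sprintf("P000%02d", 1:5)     # recovers Phosphoserine
  ids2 <- sprintf("P000%02d", 6:10)    # nothing enriched
  r1 <- enrich(db, "Testus organismus", ids1)
  r2 <- enrich(db, "Testus organismus", ids2)
  m <- match_results(r1, r2)
  expect_identical(m$rows$term_id, "ft-phosphoserine")
  expect_identical(m$rows$significant_in, "list1")
  expect_identical(m$rows$pct_list2, 0)
  # identity: every row significant in both with equal percentages
  mi <- match_results(r1, r1)
  expect_true(all(mi$rows$significant_in == "both"))
  expect_identical(mi$rows$pct_list1, mi$rows$pct_list2)
  # symmetry up to column swap
  ms <- match_results(r2, r1)
  expect_setequal(ms$rows$term_id, m$rows$term_id)
  # no significant terms anywhere -> empty matched table, context intact
  m0 <- match_results(r2, r2)
  expect_identical(nrow(m0$rows), 0L)
  expect_identical(m0$context$organism_key, "Testus organismus")
  # incomparable backgrounds are refused
  other <- build_database(list(make_record("OTH_TEST", "P99999",
                                           keywords = "Phosphoprotein")),
                          test_vocab())
  r3 <- enrich(other, "Testus organismus", "P99999")
  expect_error(match_results(r1, r3), "different",
               class = "ptmenrich_param_error")
})

test_that("table export has the documented header, round-trips, and is deterministic", {
  db <- analysis_db()
  res <- enrich(db, "Testus organismus", sprintf("P000%02d", 1:5))
  tf1 <- tempfile(fileext = ".tsv")
  export_table(res, tf1)
  lines <- readLines(tf1)
  expect_identical(lines[1L], paste(
    "ID", "PTM vocabulary", "Frequency in UniProt", "Percent in UniProt",
    "Frequency in list", "Percent in list", "UniProtKB accession numbers",
    "P-value", "Corrected P-value", sep = "\t"))
  expect_match(lines[length(lines)], "^# N=20\tn=5\talpha=0.05\tcorrection=bonferroni")
  back <- import_table(tf1)
  expect_identical(nrow(back), nrow(res$rows))
  expect_equal(back[["Percent in list"]], round(res$rows$pct_list, 2))
  expect_equal(back[["P-value"]], as.numeric(formatC(res$rows$p_value,
                                                     format = "e", digits = 3)))
  # byte-identical re-export
  tf2 <- tempfile(fileext = ".tsv")
  export_table(enrich(db, "Testus organismus", sprintf("P000%02d", 1:5)), tf2)
  expect_identical(readLines(tf1), readLines(tf2))
  # zero-row result: header and footer only
  none <- enrich(db, "Testus organismus", sprintf("P000%02d", 6:7),
                 correction = "none")
  none$rows <- none$rows[0, ]
  tf3 <- tempfile(fileext = ".tsv")
  export_table(none, tf3)
  expect_identical(length(readLines(tf3)), 2L)
})

test_that("bar charts plot the documented series", {
  db <- analysis_db()
  r1 <- enrich(db, "Testus organismus", sprintf("P000%02d", 1:5))
  tf <- tempfile(fileext = ".pdf")
  h <- export_barchart(r1, tf)
  expect_identical(length(h), nrow(r1$rows))
  expect_equal(unname(h), -log10(r1$rows$adjusted_p))
  expect_true(file.exists(tf))
  # matched results draw two bars (one per list) per term
  m <- match_results(r1, enrich(db, "Testus organismus", sprintf("P000%02d", 2:6)))
  hm <- export_barchart(m, tempfile(fileext = ".pdf"))
  expect_identical(dim(hm), c(2L, nrow(m$rows)))
  expect_identical(rownames(hm), c("list1", "list2"))
})
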