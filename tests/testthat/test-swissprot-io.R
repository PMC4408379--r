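classic_fixture <- c(
  "ID   TEST1_HUMAN             Reviewed;         100 AA.",
  "AC   P12345; Q99999;",
  "OS   Homo sapiens (Human).",
  "KW   Phosphoprotein;",
  "KW   Glycoprotein.",
  "FT   MOD_RES      10     10       Phosphoserine.",
  "DR   PhosphoSite; P12345; -.",
  "CC   -!- FUNCTION: A test protein.",
  "//"
)

test_that("classic-dialect entry parses field by field", {
  recs <- parse_entries(classic_fixture)
  expect_length(recs, 1L)
  r <- recs[[1L]]
  expect_identical(r$entry_name, "TEST1_HUMAN")
  expect_identical(r$review_status, "Reviewed")
  expect_identical(r$accessions, c("P12345", "Q99999"))
  expect_identical(r$organism_names, "Homo sapiens (Human)")
  expect_identical(r$organism_key, "Homo sapiens")
  # KW list spanning two lines is concatenated and split on ";"
  expect_setequal(r$keywords, c("Phosphoprotein", "Glycoprotein"))
  expect_identical(r$features$key, "MOD_RES")
  expect_identical(r$features$begin, 10L)
  expect_identical(r$features$end, 10L)
  expect_identical(r$features$description, "Phosphoserine")
  expect_identical(r$cross_refs$database, "PhosphoSite")
  expect_identical(r$comment_topics$topic, "FUNCTION")
  expect_identical(r$comment_topics$text, "A test protein.")
})

test_that("modern-dialect entries parse positions and /note qualifiers", {
  modern <- c(
    "ID   TEST2_HUMAN             Reviewed;         100 AA.",
    "AC   P00001;",
    "OS   Homo sapiens (Human).",
    "FT   MOD_RES         10..12",
    "FT                   /note=\"Phosphoserine\"",
    "FT                   /evidence=\"ECO:0000250\"",
    "FT   CROSSLNK        40",
    "FT                   /note=\"Glycyl lysine isopeptide\"",
    "//"
  )
  r <- parse_entries(modern)[[1L]]
  expect_identical(r$features$key, c("MOD_RES", "CROSSLNK"))
  expect_identical(r$features$begin, c(10L, 40L))
  expect_identical(r$features$end, c(12L, 40L))
  expect_identical(r$features$description,
                   c("Phosphoserine", "Glycyl lysine isopeptide"))
})

test_that("dialect detection follows the FT syntax and defaults to classic", {
  expect_identical(detect_dialect("FT   MOD_RES         10..10"), "modern")
  expect_identical(detect_dialect("FT   MOD_RES      10     10       Phosphoserine."),
                   "classic")
  expect_identical(detect_dialect(c("ID   X   Reviewed;", "KW   Transport.")),
                   "classic")
  expect_error(
    detect_dialect(c("FT   MOD_RES      10     10       Phosphoserine.",
                     "FT   MOD_RES         12..12")),
    "mixed")
})

test_that("unknown position markers parse as NA but keep the feature", {
  txt <- c(
    "ID   TEST3_YEAST             Reviewed;         100 AA.",
    "AC   P00002;",
    "OS   Saccharomyces cerevisiae.",
    "FT   MOD_RES       ?     10       Phosphoserine.",
    "FT   LIPID        <1    >90       S-palmitoyl cysteine.",
    "//"
  )
  r <- parse_entries(txt)[[1L]]
  expect_identical(r$features$begin, c(NA_integer_, 1L))
  expect_identical(r$features$end, c(10L, 90L))
  expect_identical(nrow(r$features), 2L)
})

test_that("malformed entries raise informative parse errors", {
  no_id <- c("AC   P12345;", "OS   Homo sapiens.", "//")
  expect_error(parse_entries(no_id), "no ID line", class = "ptmenrich_parse_error")
  truncated <- c(
    "ID   LAST1_HUMAN             Reviewed;         100 AA.",
    "AC   P77777;",
    "OS   Homo sapiens."
  )
  expect_error(parse_entries(truncated), "LAST1_HUMAN",
               class = "ptmenrich_parse_error")
})

test_that("write_entry produces the documented AC layout and omits empty FT", {
  r <- make_record("THREE_HUMAN", c("P00001", "P00002", "P00003"),
                   organism = "Homo sapiens (Human)")
  txt <- strsplit(write_entry(r), "\n")[[1L]]
  expect_identical(txt[startsWith(txt, "AC   ")], "AC   P00001; P00002; P00003;")
  expect_false(any(startsWith(txt, "FT   ")))
  r2 <- make_record("NL_HUMAN", "P00004",
                    comment_topics = data.frame(topic = "FUNCTION",
                                                text = "bad\ntext"))
  expect_error(write_entry(r2), "line terminators",
               class = "ptmenrich_write_error")
})

test_that("write -> parse is the identity on random records in both dialects", {
  set.seed(101)
  for (dialect in c("classic", "modern")) {
    records <- lapply(1:40, random_record)
    reparsed <- parse_entries(write_entries(records, dialect = dialect),
                              dialect = dialect)
    expect_identical(reparsed, records)
  }
})

test_that("parsing streams entries through a callback without accumulating them", {
  entry <- paste(c("ID   MINI_HUMAN              Reviewed;         100 AA.",
                   "AC   P55555;",
                   "OS   Homo sapiens.",
                   "KW   Phosphoprotein.",
                   "//"), collapse = "\n")
  big <- paste(rep(entry, 2000L), collapse = "\n")
  seen <- 0L
  n <- parse_entries(big, callback = function(rec) {
    seen <<- seen + 1L
    expect_identical(rec$entry_name, "MINI_HUMAN")
  })
  expect_identical(n, 2000L)
  expect_identical(seen, 2000L)
})

test_that("CC topics are retained verbatim and never mined for PTM terms", {
  txt <- c(
    "ID   CCONLY_HUMAN            Reviewed;         100 AA.",
    "AC   P31337;",
    "OS   Homo sapiens.",
    "CC   -!- PTM: Phosphoserine at position 10.",
    "//"
  )
  r <- parse_entries(txt)[[1L]]
  expect_identical(r$comment_topics$text, "Phosphoserine at position 10.")
  db <- build_database(list(r), test_vocab())
  expect_identical(nrow(db$proteins), 0L)
})
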