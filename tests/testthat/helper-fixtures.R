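# Shared fixture builders: all fixtures are constructed in code at test time.

rand_accession <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(LETTERS, 1L),
           paste(sample(c(LETTERS, as.character(0:9)), 5L, replace = TRUE),
                 collapse = ""))
  }, character(1))
}

# A random but valid protein record exercising the odd corners of the format:
# multiple accessions, unknown feature positions, qualifiers, DR and CC lines.
random_record <- function(i = 1L) {
  accs <- unique(rand_accession(sample(1:3, 1L)))
  kw_pool <- c("Phosphoprotein", "Glycoprotein", "Acetylation", "Transport",
               "Zinc finger", "Ubl conjugation")
  kws <- sample(kw_pool, sample(0:3, 1L))
  nf <- sample(0:3, 1L)
  features <- if (nf > 0L) {
    begin <- sample(c(NA_integer_, 1:200), nf, replace = TRUE)
    end <- ifelse(is.na(begin), NA_integer_, begin + sample(0:5, nf, replace = TRUE))
    data.frame(
      key = sample(c("MOD_RES", "LIPID", "CROSSLNK", "CARBOHYD", "DISULFID"),
                   nf, replace = TRUE),
      begin = begin, end = end,
      description = sample(c("Phosphoserine", "N6-acetyllysine",
                             "Phosphoserine (By similarity)",
                             "S-palmitoyl cysteine; by PAT1",
                             "Some modified residue", ""),
                           nf, replace = TRUE),
      stringsAsFactors = FALSE
    )
  } else ptmenrich:::empty_features()
  ndr <- sample(0:2, 1L)
  cross_refs <- if (ndr > 0L) {
    data.frame(database = sample(c("PhosphoSite", "UniCarbKB", "PDB"), ndr),
               id = rand_accession(ndr), stringsAsFactors = FALSE)
  } else ptmenrich:::empty_cross_refs()
  ncc <- sample(0:2, 1L)
  topics <- if (ncc > 0L) {
    data.frame(topic = sample(c("FUNCTION", "SIMILARITY"), ncc),
               text = replicate(ncc, paste(sample(letters, 12L, TRUE), collapse = "")),
               stringsAsFactors = FALSE)
  } else ptmenrich:::empty_comment_topics()
  protein_record(
    entry_name = sprintf("RR%04d_%s", i, sample(c("HUMAN", "MOUSE", "YEAST"), 1L)),
    accessions = accs,
    organism_names = sample(c("Homo sapiens (Human)", "Mus musculus (Mouse)",
                              "Saccharomyces cerevisiae"), 1L),
    keywords = kws,
    features = features,
    cross_refs = cross_refs,
    comment_topics = topics,
    review_status = sample(c("Reviewed", "Reviewed", "Unreviewed"), 1L)
  )
}

# tiny record with everything defaulted; handy for database-rule tests
make_record <- function(entry_name, accession, organism = "Testus organismus",
                        keywords = character(), features = NULL,
                        cross_refs = NULL, review_status = "Reviewed",
                        comment_topics = NULL) {
  protein_record(
    entry_name = entry_name, accessions = accession,
    organism_names = organism, keywords = keywords,
    features = features %||% ptmenrich:::empty_features(),
    cross_refs = cross_refs %||% ptmenrich:::empty_cross_refs(),
    comment_topics = comment_topics %||% ptmenrich:::empty_comment_topics(),
    review_status = review_status
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mod_res <- function(description, begin = 10L, key = "MOD_RES") {
  data.frame(key = key, begin = begin, end = begin, description = description,
             stringsAsFactors = FALSE)
}

# small two-level vocabulary used in many database tests
test_vocab <- function() {
  load_vocabulary(
    kw_terms = c("Phosphoprotein", "Glycoprotein", "Acetylation"),
    ft_terms = c("Phosphoserine", "Phosphothreonine", "N6-acetyllysine"),
    edges = data.frame(
      ft = c("Phosphoserine", "Phosphothreonine", "N6-acetyllysine"),
      kw = c("Phosphoprotein", "Phosphoprotein", "Acetylation"),
      stringsAsFactors = FALSE
    )
  )
}

# Independent exhaustive oracle for the hypergeometric upper tail:
# enumerate all C(N, n) draws and count those with >= m successes.
enum_tail_prob <- function(N, K, n, m) {
  if (m == 0L) return(1)
  if (n == 0L) return(if (m == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  successes <- matrix(draws <= K, nrow = nrow(draws))
  mean(colSums(successes) >= m)
}

# random 3-level DAG for XML round-trip property tests
random_dag <- function() {
  nkw <- sample(1:4, 1L)
  nft <- sample(0:6, 1L)
  kw <- paste0("KW term ", seq_len(nkw))
  ft <- if (nft > 0L) paste0("FT term ", seq_len(nft)) else character()
  edges <- NULL
  if (nft > 0L) {
    edges <- do.call(rbind, lapply(ft, function(f) {
      parents <- sample(kw, sample(seq_len(min(2L, nkw)), 1L))
      data.frame(ft = f, kw = parents, stringsAsFactors = FALSE)
    }))
  }
  build_dag(load_vocabulary(kw, ft, edges))
}
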