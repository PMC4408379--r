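# Synthetic Swiss-Prot fixture generation with known ground truth, plus
# planted-enrichment protein lists. Annotations are sampled independently per
# term — adequate for calibration and recovery testing, not a model of real
# PTM co-occurrence. Sequence content is not generated (SQ lines are not
# needed by the parser).

#' Specification of a synthetic Swiss-Prot fixture
#'
#' Default prevalences sketch a Swiss-Prot-like mix: a handful of common
#' keyword categories (phosphoprotein ~30%, glycoprotein ~20%, ...) and
#' twelve feature-level modified-residue terms at 2-15%, for 20 terms in
#' total over 2,000 proteins in one organism.
#'
#' @param n_proteins Proteins per organism.
#' @param organisms Character vector of organism names.
#' @param kw_probs Named numeric vector: keyword-level term label ->
#'   annotation probability.
#' @param ft_probs Named numeric vector: feature-level term label ->
#'   annotation probability.
#' @param putative_fraction Probability that an emitted feature carries a
#'   `(By similarity)` qualifier (putative evidence).
#' @param dialect Feature-table dialect for [write_entries].
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 2000L,
                         organisms = "Synthetica testudinis",
                         kw_probs = c(
                           "Phosphoprotein" = 0.30, "Glycoprotein" = 0.20,
                           "Disulfide bond" = 0.15, "Acetylation" = 0.12,
                           "Nucleotide-binding" = 0.10, "Methylation" = 0.06,
                           "Lipoprotein" = 0.05, "Ubl conjugation" = 0.05),
                         ft_probs = c(
                           "Phosphoserine" = 0.15, "Phosphothreonine" = 0.08,
                           "N6-acetyllysine" = 0.06, "Phosphotyrosine" = 0.05,
                           "Phosphohistidine" = 0.05, "N-acetylalanine" = 0.04,
                           "N-acetylmethionine" = 0.03, "N6-succinyllysine" = 0.03,
                           "S-palmitoyl cysteine" = 0.03,
                           "Glycyl lysine isopeptide" = 0.02,
                           "O-linked glycosylation" = 0.02,
                           "N6-(pyridoxal phosphate)lysine" = 0.02),
                         putative_fraction = 0.2,
                         dialect = c("classic", "modern"),
                         seed = 1L) {
  dialect <- match.arg(dialect)
  if (!is_count(n_proteins) || n_proteins < 1L) {
    ptm_error("fixture_spec: n_proteins must be a positive integer",
              "ptmenrich_param_error")
  }
  probs <- c(kw_probs, ft_probs, putative_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    ptm_error("fixture_spec: probabilities must lie in [0, 1]",
              "ptmenrich_param_error")
  }
  structure(list(n_proteins = as.integer(n_proteins), organisms = organisms,
                 kw_probs = kw_probs, ft_probs = ft_probs,
                 putative_fraction = putative_fraction, dialect = dialect,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# UniProt accession grammar (simplified): letter + 5 alphanumerics
generate_accessions <- function(n) {
  repeat {
    acc <- paste0(
      sample(LETTERS, n, replace = TRUE),
      apply(matrix(sample(c(LETTERS, 0:9), 5L * n, replace = TRUE), ncol = 5L),
            1L, paste, collapse = "")
    )
    if (!anyDuplicated(acc)) return(acc)
  }
}

ft_key_for_term <- function(label) {
  l <- tolower(label)
  if (grepl("palmitoyl|diacylglycerol|myristoyl", l)) "LIPID"
  else if (grepl("isopeptide|ubiquitin|interchain", l)) "CROSSLNK"
  else "MOD_RES"
}

#' Generate synthetic Swiss-Prot records with ground truth
#'
#' Each protein receives each keyword-level term independently with its
#' `kw_probs` probability and each feature-level term with its `ft_probs`
#' probability; emitted features carry a `(By similarity)` qualifier with
#' probability `putative_fraction`. The returned truth table exactly matches
#' the emitted annotations, and regeneration with the same seed is
#' byte-identical.
#'
#' @param spec A [fixture_spec].
#' @return List with `records` (list of [protein_record]) and `truth`
#'   (`data.frame`: `organism`, `accession`, `level`, `label`, `qualifier`).
#' @export
generate_records <- function(spec) {
  if (!inherits(spec, "fixture_spec")) spec <- do.call(fixture_spec, spec)
  with_seed(spec$seed, {
    records <- list()
    t_org <- character(); t_acc <- character(); t_level <- character()
    t_label <- character(); t_qual <- character()
    for (org_i in seq_along(spec$organisms)) {
      org <- spec$organisms[[org_i]]
      org_code <- toupper(substr(gsub("[^A-Za-z]", "", org), 1L, 5L))
      n <- spec$n_proteins
      accs <- generate_accessions(n)
      kw_hits <- matrix(stats::runif(n * length(spec$kw_probs)) <
                          rep(spec$kw_probs, each = n), nrow = n)
      ft_hits <- matrix(stats::runif(n * length(spec$ft_probs)) <
                          rep(spec$ft_probs, each = n), nrow = n)
      for (i in seq_len(n)) {
        kws <- names(spec$kw_probs)[kw_hits[i, ]]
        fts <- names(spec$ft_probs)[ft_hits[i, ]]
        quals <- character(0)
        features <- empty_features()
        if (length(fts)) {
          putative <- stats::runif(length(fts)) < spec$putative_fraction
          quals <- ifelse(putative, "Putative", "Experimental")
          pos <- sample.int(400L, length(fts), replace = TRUE)
          features <- data.frame(
            key = vapply(fts, ft_key_for_term, character(1)),
            begin = pos, end = pos,
            description = paste0(fts, ifelse(putative, " (By similarity)", "")),
            stringsAsFactors = FALSE
          )
        }
        cross_refs <- empty_cross_refs()
        if (any(grepl("^Phospho", fts)) && stats::runif(1) < 0.5) {
          cross_refs <- data.frame(database = "PhosphoSite", id = accs[i],
                                   stringsAsFactors = FALSE)
        }
        rec <- protein_record(
          entry_name = sprintf("PR%04d_%s", i, org_code),
          accessions = accs[i],
          organism_names = org,
          keywords = kws,
          features = features,
          cross_refs = cross_refs
        )
        records[[length(records) + 1L]] <- rec
        n_ann <- length(kws) + length(fts)
        if (n_ann) {
          t_org <- c(t_org, rep(org, n_ann))
          t_acc <- c(t_acc, rep(accs[i], n_ann))
          t_level <- c(t_level, rep(c("KW", "FT"), c(length(kws), length(fts))))
          t_label <- c(t_label, kws, fts)
          t_qual <- c(t_qual, rep(NA_character_, length(kws)), quals)
        }
      }
    }
    truth <- data.frame(organism = t_org, accession = t_acc, level = t_level,
                        label = t_label, qualifier = t_qual,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Specification of a planted-enrichment list
#'
#' @param term Target term label (as it appears in the truth table).
#' @param n List size.
#' @param f Enrichment factor (>= 1): carriers of the term are oversampled so
#'   the expected list prevalence is `min(1, f * background prevalence)`.
#' @param seed Integer seed.
#' @return A list of class `planted_list_spec`.
#' @export
planted_list_spec <- function(term, n, f = 1, seed = 1L) {
  if (!is_count(n) || n < 1L) {
    ptm_error("planted_list_spec: n must be a positive integer",
              "ptmenrich_param_error")
  }
  if (!is.numeric(f) || f < 1) {
    ptm_error("planted_list_spec: enrichment factor f must be >= 1",
              "ptmenrich_param_error")
  }
  structure(list(term = term, n = as.integer(n), f = f, seed = as.integer(seed)),
            class = "planted_list_spec")
}

#' Sample a protein list with a planted enriched term
#'
#' Draws `n` accessions without replacement from one organism of a fixture
#' truth table. With enrichment factor `f = 1` the list is a plain uniform
#' background sample (the null case). For `f > 1` the number of
#' term-carrying members is drawn as Binomial(`n`, `min(1, f p)`) — `p` being
#' the background prevalence — clamped to feasibility, so the expected list
#' prevalence equals the specification. The returned ids are shuffled
#' deterministically by the seed.
#'
#' @param truth Truth table from [generate_records] (or any `data.frame` with
#'   `organism`, `accession`, `label` columns describing the background).
#' @param spec A [planted_list_spec].
#' @param organism Organism partition to sample from (default: the first in
#'   the truth table).
#' @return Character vector of `n` accessions.
#' @export
plant_enriched_list <- function(truth, spec, organism = NULL) {
  organism <- organism %||% truth$organism[1L]
  part <- truth[truth$organism == organism, , drop = FALSE]
  pool <- sort(unique(part$accession))
  carriers <- sort(unique(part$accession[part$label == spec$term]))
  if (length(carriers) == 0L) {
    ptm_error(sprintf("term '%s' has zero prevalence in the background", spec$term),
              "ptmenrich_param_error")
  }
  non_carriers <- setdiff(pool, carriers)
  if (spec$n > length(pool)) {
    ptm_error("list size n exceeds the organism partition", "ptmenrich_param_error")
  }
  p <- length(carriers) / length(pool)
  q <- min(1, spec$f * p)
  if (spec$f * p > 1 && spec$n > length(carriers)) {
    ptm_error(sprintf(
      "infeasible prevalence: f * p = %.3f > 1 with n = %d exceeding the %d carrier(s)",
      spec$f * p, spec$n, length(carriers)), "ptmenrich_param_error")
  }
  with_seed(spec$seed, {
    if (spec$f == 1) {
      ids <- sample(pool, spec$n)
    } else {
      k <- stats::rbinom(1L, spec$n, q)
      k <- min(k, length(carriers), spec$n)
      k <- max(k, spec$n - length(non_carriers))
      ids <- c(sample(carriers, k),
               if (spec$n - k > 0L) sample(non_carriers, spec$n - k))
      ids <- sample(ids)
    }
    ids
  })
}

#' Emit a complete fixture set to a directory
#'
#' Writes the synthetic DAT file, the packaged vocabulary, the truth table
#' (tab-delimited) and a ready planted protein list. Used by the
#' `make-fixtures` CLI subcommand.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec].
#' @param list_spec A [planted_list_spec]; default plants "Phosphotyrosine"
#'   (a low-prevalence term, so five-fold oversampling stays feasible) in a
#'   list of 100.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_set <- function(dir, spec = fixture_spec(),
                              list_spec = planted_list_spec("Phosphotyrosine",
                                                            n = 100L, f = 5,
                                                            seed = spec$seed)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_records(spec)
  paths <- c(
    dat = file.path(dir, "synthetic_sprot.dat"),
    vocabulary = file.path(dir, "vocabulary.tsv"),
    truth = file.path(dir, "truth.tsv"),
    list = file.path(dir, "planted_list.txt")
  )
  write_entries(gen$records, dialect = spec$dialect, path = paths[["dat"]])
  write_vocabulary(default_vocabulary(), paths[["vocabulary"]])
  utils::write.table(gen$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ids <- plant_enriched_list(gen$truth, list_spec)
  writeLines(c("# synthetic planted list", ids), paths[["list"]])
  invisible(paths)
}
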