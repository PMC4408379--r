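# User-facing analyses: single-list PTM enrichment, two-list integration and
# matching, list frequency analysis, and table / bar-chart export.

DEFAULT_MARKER_MAP <- c(phossite = 1L, phosphosite = 2L, unicarbkb = 3L)

#' Cross-reference markers for a record
#'
#' Maps DR database names onto the numeric markers rendered next to
#' accessions in result tables: by default 1 for PhosSite, 2 for PhosphoSite
#' and 3 for UniCarbKB. Matching is case-insensitive substring matching, so
#' e.g. "PhosphoSitePlus" also yields marker 2.
#'
#' @param record A [protein_record].
#' @param marker_map Named integer vector; names are lower-case substrings to
#'   search for in DR database names.
#' @return Sorted integer vector of markers (possibly empty).
#' @export
crossref_markers <- function(record, marker_map = DEFAULT_MARKER_MAP) {
  dbs <- tolower(record$cross_refs$database)
  hits <- vapply(names(marker_map),
                 function(p) any(grepl(p, dbs, fixed = TRUE)), logical(1))
  sort(unique(unname(marker_map[hits])))
}

render_markers <- function(markers) {
  if (length(markers) == 0L) return("")
  paste0("(", markers, ")", collapse = "")
}

# shared front end of enrich()/list_frequency(): resolve the list and gather
# per-term background and list counts
gather_counts <- function(db, organism_key, raw_ids) {
  res <- resolve_proteins(db, organism_key, raw_ids)
  matched <- res$matched
  N <- organism_size(db, organism_key)
  idx <- db$term_index[[organism_key]] %||% list()
  term_ids <- sort(names(idx))
  K <- vapply(term_ids, function(t) length(idx[[t]]), integer(1))
  m <- vapply(term_ids, function(t) length(intersect(idx[[t]], matched)), integer(1))
  members <- lapply(term_ids, function(t) intersect(matched, idx[[t]]))
  markers <- db$proteins$markers[db$proteins$organism == organism_key]
  names(markers) <- db$proteins$accession[db$proteins$organism == organism_key]
  member_str <- vapply(members, function(a) {
    paste0(a, markers[a], collapse = "; ")
  }, character(1))
  list(matched = matched, unmatched = res$unmatched, N = N, n = length(matched),
       term_id = term_ids,
       label = db$terms$label[match(term_ids, db$terms$term_id)],
       K = unname(K), m = unname(m), members = unname(member_str))
}

#' PTM enrichment analysis of a protein list
#'
#' Resolves the identifiers within the organism partition, computes for every
#' testable term (background count `K >= 1`) the exact hypergeometric tail
#' probability of observing at least `m` of the `n` list proteins with the
#' term, applies the chosen multiple-testing correction across the `T`
#' testable terms, and returns the rows with at least one list hit, ordered
#' by increasing p-value (ties by label). Terms absent from the list
#' (`m = 0`, p = 1 by construction) are kept in the `all_terms` table, which
#' two-list matching uses, but excluded from the display rows.
#'
#' @param db A `ptm_database`.
#' @param organism_key Organism to analyse.
#' @param raw_ids Character vector of protein identifiers.
#' @param alpha Significance level in (0, 1).
#' @param correction `"bonferroni"` (default), `"bh"` or `"none"`.
#' @return An `enrichment_result`: `rows` (the display table), `all_terms`,
#'   and a `context` list (organism, `N`, `n`, unmatched ids, alpha,
#'   correction, adjusted alpha for Bonferroni, number of tests `T`, database
#'   fingerprint).
#' @export
enrich <- function(db, organism_key, raw_ids, alpha = 0.05,
                   correction = c("bonferroni", "bh", "none")) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    ptm_error("alpha must lie strictly between 0 and 1", "ptmenrich_param_error")
  }
  g <- gather_counts(db, organism_key, raw_ids)
  n_tests <- length(g$term_id)
  p <- vapply(seq_len(n_tests), function(i) {
    as.numeric(hypergeom_pvalue(g$N, g$K[i], g$n, g$m[i]))
  }, numeric(1))
  adjusted_alpha <- NA_real_
  adj <- rep(NA_real_, n_tests)
  if (n_tests > 0L) {
    if (correction == "bonferroni") {
      b <- bonferroni_adjust(p, alpha)
      adj <- b$adjusted
      adjusted_alpha <- b$adjusted_alpha
    } else if (correction == "bh") {
      adj <- bh_adjust(p)
    }
  }
  decision_p <- if (correction == "none") p else adj
  all_terms <- data.frame(
    term_id = g$term_id, term_label = g$label,
    freq_db = g$K, pct_db = 100 * g$K / g$N,
    freq_list = g$m, pct_list = 100 * g$m / g$n,
    members = g$members, p_value = p, adjusted_p = adj,
    significant = decision_p <= alpha,
    stringsAsFactors = FALSE
  )
  rows <- all_terms[all_terms$freq_list > 0L, , drop = FALSE]
  rows <- rows[order(rows$p_value, rows$term_label), , drop = FALSE]
  rownames(rows) <- NULL
  rownames(all_terms) <- NULL
  structure(
    list(rows = rows, all_terms = all_terms,
         context = list(organism_key = organism_key, N = g$N, n = g$n,
                        unmatched = g$unmatched, alpha = alpha,
                        correction = correction, adjusted_alpha = adjusted_alpha,
                        n_tests = n_tests, db_fingerprint = db$fingerprint)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  ctx <- x$context
  cat(sprintf("<enrichment_result> %s: n = %d of N = %d; %d term(s) tested (%s, alpha = %g)\n",
              ctx$organism_key, ctx$n, ctx$N, ctx$n_tests, ctx$correction,
              ctx$alpha))
  cat(sprintf("  %d term(s) with list hits, %d significant; %d unmatched id(s)\n",
              nrow(x$rows), sum(x$rows$significant), length(ctx$unmatched)))
  invisible(x)
}

#' Integrate and match two enrichment results
#'
#' Takes the union of the terms significant in either result (the
#' `significant_in` column recovers the intersection view) and tabulates both
#' lists' percentages and raw/adjusted p-values side by side. Both results
#' must come from the same database and organism, otherwise the backgrounds
#' are incomparable and an error is raised.
#'
#' @param result1,result2 `enrichment_result` objects from [enrich].
#' @return A `matched_result` with `rows` (term, `pct_list1`, `pct_list2`,
#'   `p1`, `p2`, `adj_p1`, `adj_p2`, `significant_in`) and a `context` list.
#' @export
match_results <- function(result1, result2) {
  c1 <- result1$context; c2 <- result2$context
  if (!identical(c1$organism_key, c2$organism_key) ||
      !identical(c1$db_fingerprint, c2$db_fingerprint)) {
    ptm_error("results were computed against different organisms or databases",
              "ptmenrich_param_error")
  }
  a1 <- result1$all_terms; a2 <- result2$all_terms
  sig <- union(a1$term_id[a1$significant], a2$term_id[a2$significant])
  pick <- function(a, ids) a[match(ids, a$term_id), , drop = FALSE]
  r1 <- pick(a1, sig); r2 <- pick(a2, sig)
  sig_in <- ifelse(r1$significant & r2$significant, "both",
                   ifelse(r1$significant, "list1", "list2"))
  rows <- data.frame(
    term_id = sig, term_label = r1$term_label,
    pct_list1 = r1$pct_list, pct_list2 = r2$pct_list,
    p1 = r1$p_value, p2 = r2$p_value,
    adj_p1 = r1$adjusted_p, adj_p2 = r2$adjusted_p,
    significant_in = sig_in, stringsAsFactors = FALSE
  )
  rows <- rows[order(pmin(rows$p1, rows$p2), rows$term_label), , drop = FALSE]
  rownames(rows) <- NULL
  structure(
    list(rows = rows,
         context = list(organism_key = c1$organism_key, N = c1$N,
                        n1 = c1$n, n2 = c2$n, alpha = c1$alpha,
                        correction = c1$correction,
                        db_fingerprint = c1$db_fingerprint)),
    class = "matched_result"
  )
}

#' @export
print.matched_result <- function(x, ...) {
  cat(sprintf("<matched_result> %s: %d matched term(s) (n1 = %d, n2 = %d)\n",
              x$context$organism_key, nrow(x$rows), x$context$n1, x$context$n2))
  invisible(x)
}

#' PTM frequency analysis of a protein list
#'
#' For every term present in the organism background (`K > 0`), reports the
#' organism frequency and percentage and the list frequency and percentage —
#' no hypothesis testing. Terms missing from the list are reported with
#' `freq_list = 0`.
#'
#' @inheritParams enrich
#' @return A `frequency_result` with `rows` (`term_id`, `term_label`,
#'   `freq_db`, `pct_db`, `freq_list`, `pct_list`) and `context`.
#' @export
list_frequency <- function(db, organism_key, raw_ids) {
  g <- gather_counts(db, organism_key, raw_ids)
  rows <- data.frame(
    term_id = g$term_id, term_label = g$label,
    freq_db = g$K, pct_db = 100 * g$K / g$N,
    freq_list = g$m, pct_list = 100 * g$m / g$n,
    members = g$members, stringsAsFactors = FALSE
  )
  rows <- rows[order(-rows$freq_list, -rows$freq_db, rows$term_label), ,
               drop = FALSE]
  rownames(rows) <- NULL
  structure(
    list(rows = rows,
         context = list(organism_key = g$organism_key %||% organism_key,
                        N = g$N, n = g$n, unmatched = g$unmatched,
                        alpha = NA_real_, correction = "none",
                        adjusted_alpha = NA_real_,
                        db_fingerprint = db$fingerprint)),
    class = "frequency_result"
  )
}

#' @export
print.frequency_result <- function(x, ...) {
  cat(sprintf("<frequency_result> %s: %d term(s); n = %d of N = %d\n",
              x$context$organism_key, nrow(x$rows), x$context$n, x$context$N))
  invisible(x)
}

fmt_pct <- function(x) sprintf("%.2f", x)
fmt_p <- function(x) ifelse(is.na(x), "", formatC(x, format = "e", digits = 3))

result_footer <- function(ctx) {
  paste0("# N=", ctx$N,
         "\tn=", ctx$n %||% ctx$n1,
         "\talpha=", ctx$alpha,
         "\tcorrection=", ctx$correction,
         "\tadjusted_alpha=",
         if (is.na(ctx$adjusted_alpha %||% NA_real_)) "NA" else
           formatC(ctx$adjusted_alpha, format = "e", digits = 3))
}

ENRICH_HEADER <- paste("ID", "PTM vocabulary", "Frequency in UniProt",
                       "Percent in UniProt", "Frequency in list",
                       "Percent in list", "UniProtKB accession numbers",
                       "P-value", "Corrected P-value", sep = "\t")

#' Export a result as a delimited text table
#'
#' Enrichment results use the fixed header `ID`, `PTM vocabulary`,
#' `Frequency in UniProt`, `Percent in UniProt`, `Frequency in list`,
#' `Percent in list`, `UniProtKB accession numbers` (with cross-reference
#' markers appended), `P-value`, `Corrected P-value`. Percentages are printed
#' with 2 decimals and p-values in scientific notation with 4 significant
#' digits. A `#` footer line records `N`, `n`, alpha, the correction and the
#' adjusted alpha. Identical inputs produce byte-identical files.
#'
#' @param result An `enrichment_result`, `matched_result` or
#'   `frequency_result`.
#' @param destination File path.
#' @return `destination`, invisibly.
#' @export
export_table <- function(result, destination) UseMethod("export_table")

#' @export
export_table.enrichment_result <- function(result, destination) {
  r <- result$rows
  lines <- c(ENRICH_HEADER,
             if (nrow(r)) paste(r$term_id, r$term_label, r$freq_db,
                                fmt_pct(r$pct_db), r$freq_list,
                                fmt_pct(r$pct_list), r$members,
                                fmt_p(r$p_value), fmt_p(r$adjusted_p),
                                sep = "\t"),
             result_footer(result$context))
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}

#' @export
export_table.frequency_result <- function(result, destination) {
  r <- result$rows
  lines <- c(ENRICH_HEADER,
             if (nrow(r)) paste(r$term_id, r$term_label, r$freq_db,
                                fmt_pct(r$pct_db), r$freq_list,
                                fmt_pct(r$pct_list), r$members, "", "",
                                sep = "\t"),
             result_footer(result$context))
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}

#' @export
export_table.matched_result <- function(result, destination) {
  r <- result$rows
  header <- paste("ID", "PTM vocabulary", "Percent in list 1",
                  "Percent in list 2", "P-value list 1", "P-value list 2",
                  "Corrected P-value list 1", "Corrected P-value list 2",
                  "Significant in", sep = "\t")
  lines <- c(header,
             if (nrow(r)) paste(r$term_id, r$term_label, fmt_pct(r$pct_list1),
                                fmt_pct(r$pct_list2), fmt_p(r$p1), fmt_p(r$p2),
                                fmt_p(r$adj_p1), fmt_p(r$adj_p2),
                                r$significant_in, sep = "\t"),
             paste0("# N=", result$context$N,
                    "\tn1=", result$context$n1, "\tn2=", result$context$n2,
                    "\talpha=", result$context$alpha,
                    "\tcorrection=", result$context$correction))
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}

#' Re-import an exported result table
#'
#' Reads a table written by [export_table] back into a `data.frame` at the
#' printed precision (numeric columns parsed, footer ignored). Intended for
#' round-trip checks and downstream scripting.
#'
#' @param path Exported file path.
#' @return A `data.frame`.
#' @export
import_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(lines, collapse = "\n"), check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
}

#' Export a result as a vector-graphic bar chart
#'
#' Enrichment results plot `-log10` of the decision p-value (adjusted when a
#' correction is in effect) per term; matched results plot the two lists'
#' percentages as paired bars; frequency results plot list versus organism
#' percentages.
#'
#' @param result A result object.
#' @param destination PDF file path.
#' @return Invisibly, the numeric data plotted (vector or matrix), for
#'   structural inspection.
#' @export
export_barchart <- function(result, destination) UseMethod("export_barchart")

barchart_device <- function(destination, code) {
  grDevices::pdf(destination, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  force(code)
}

#' @export
export_barchart.enrichment_result <- function(result, destination) {
  r <- result$rows
  dec <- if (result$context$correction == "none") r$p_value else r$adjusted_p
  h <- stats::setNames(-log10(dec), r$term_label)
  barchart_device(destination, {
    graphics::par(mar = c(10, 4, 2, 1))
    graphics::barplot(h, las = 2, ylab = "-log10(p)",
                      main = sprintf("PTM enrichment (%s)",
                                     result$context$organism_key))
    graphics::abline(h = -log10(result$context$alpha), lty = 2)
  })
  invisible(h)
}

#' @export
export_barchart.matched_result <- function(result, destination) {
  r <- result$rows
  m <- rbind(list1 = r$pct_list1, list2 = r$pct_list2)
  colnames(m) <- r$term_label
  barchart_device(destination, {
    graphics::par(mar = c(10, 4, 2, 1))
    graphics::barplot(m, beside = TRUE, las = 2, ylab = "Percent in list",
                      legend.text = rownames(m),
                      main = "Matched PTM terms")
  })
  invisible(m)
}

#' @export
export_barchart.frequency_result <- function(result, destination) {
  r <- result$rows
  m <- rbind(organism = r$pct_db, list = r$pct_list)
  colnames(m) <- r$term_label
  barchart_device(destination, {
    graphics::par(mar = c(10, 4, 2, 1))
    graphics::barplot(m, beside = TRUE, las = 2, ylab = "Percent",
                      legend.text = rownames(m),
                      main = sprintf("PTM frequencies (%s)",
                                     result$context$organism_key))
  })
  invisible(m)
}
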