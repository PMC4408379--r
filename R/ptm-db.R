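# Curation of the PTM database from parsed Swiss-Prot records: filter
# PTM-annotated reviewed proteins, index them by organism and vocabulary
# term, and compute the curation statistics (annotation-source Venn, feature
# key composition, term frequencies, evidence dictionaries).

DEFAULT_FT_KEYS <- c("MOD_RES", "LIPID", "CROSSLNK")
UNCATEGORIZED_ID <- "uncategorized"

#' Build a PTM database from parsed records
#'
#' A reviewed protein enters the database iff at least one of its keywords
#' matches a KW-level vocabulary term (case-insensitively), or at least one
#' feature whose key is in `ft_keys` yields a non-empty normalized
#' description (see [normalize_ft_description]). Unreviewed records are
#' excluded. Normalized feature descriptions that match no FT-level
#' vocabulary label are kept as ad-hoc FT terms under a synthetic
#' "Uncategorized" keyword parent, so no annotation is silently dropped.
#'
#' The database is the enrichment background: `N` for an organism is the
#' number of its PTM-annotated proteins, not the whole proteome. This
#' materially affects p-values and is the convention used throughout.
#'
#' Building is deterministic and order-independent: permuting the input
#' records yields an identical database.
#'
#' @param records List of [protein_record] objects.
#' @param vocab A `ptm_vocabulary`.
#' @param ft_keys Feature keys mined for PTM terms.
#' @return A `ptm_database`.
#' @export
build_database <- function(records, vocab, ft_keys = DEFAULT_FT_KEYS) {
  if (missing(vocab) || is.null(vocab) || !inherits(vocab, "ptm_vocabulary")) {
    ptm_error("build_database requires a ptm_vocabulary", "ptmenrich_db_error")
  }
  prot_org <- character(); prot_acc <- character(); prot_name <- character()
  prot_tag <- character(); prot_markers <- character()
  al_org <- character(); al_alias <- character(); al_acc <- character()
  ti_org <- character(); ti_term <- character(); ti_acc <- character()
  ev_org <- character(); ev_acc <- character(); ev_term <- character()
  ev_qual <- character()
  fk_org <- character(); fk_acc <- character(); fk_key <- character()
  adhoc_id <- character(); adhoc_label <- character()

  for (rec in records) {
    if (!inherits(rec, "protein_record")) {
      ptm_error("build_database expects protein_record objects", "ptmenrich_db_error")
    }
    if (rec$review_status != "Reviewed") next
    org <- rec$organism_key
    if (is.na(org)) next
    acc <- rec$accessions[[1L]]

    kw_ids <- vocab_lookup(vocab, rec$keywords, "KW")
    kw_ids <- unique(kw_ids[!is.na(kw_ids)])

    f <- rec$features[rec$features$key %in% ft_keys, , drop = FALSE]
    ft_ids <- character(); ft_quals <- character(); keys_here <- character()
    if (nrow(f)) {
      norm <- normalize_ft_description(f$description)
      ok <- !is.na(norm$label)
      if (any(ok)) {
        labs <- norm$label[ok]
        ids <- vocab_lookup(vocab, labs, "FT")
        miss <- is.na(ids)
        if (any(miss)) {
          ids[miss] <- paste0("ft-", slugify(labs[miss]))
          adhoc_id <- c(adhoc_id, ids[miss])
          adhoc_label <- c(adhoc_label, labs[miss])
        }
        ft_ids <- ids
        ft_quals <- norm$qualifier[ok]
        keys_here <- unique(f$key[ok])
      }
    }

    has_kw <- length(kw_ids) > 0L
    has_ft <- length(ft_ids) > 0L
    if (!has_kw && !has_ft) next

    prot_org <- c(prot_org, org)
    prot_acc <- c(prot_acc, acc)
    prot_name <- c(prot_name, rec$entry_name)
    prot_tag <- c(prot_tag,
                  if (has_kw && has_ft) "Both" else if (has_kw) "KW-only" else "FT-only")
    prot_markers <- c(prot_markers, render_markers(crossref_markers(rec)))

    aliases <- unique(tolower(c(rec$accessions, rec$entry_name)))
    al_org <- c(al_org, rep(org, length(aliases)))
    al_alias <- c(al_alias, aliases)
    al_acc <- c(al_acc, rep(acc, length(aliases)))

    terms_here <- unique(c(kw_ids, ft_ids))
    ti_org <- c(ti_org, rep(org, length(terms_here)))
    ti_term <- c(ti_term, terms_here)
    ti_acc <- c(ti_acc, rep(acc, length(terms_here)))

    if (has_ft) {
      evp <- unique(data.frame(term = ft_ids, qual = ft_quals,
                               stringsAsFactors = FALSE))
      ev_org <- c(ev_org, rep(org, nrow(evp)))
      ev_acc <- c(ev_acc, rep(acc, nrow(evp)))
      ev_term <- c(ev_term, evp$term)
      ev_qual <- c(ev_qual, evp$qual)
      fk_org <- c(fk_org, rep(org, length(keys_here)))
      fk_acc <- c(fk_acc, rep(acc, length(keys_here)))
      fk_key <- c(fk_key, keys_here)
    }
  }

  proteins <- data.frame(organism = prot_org, accession = prot_acc,
                         entry_name = prot_name, source_tag = prot_tag,
                         markers = prot_markers, stringsAsFactors = FALSE)
  o <- order(proteins$organism, proteins$accession)
  proteins <- proteins[o, , drop = FALSE]
  rownames(proteins) <- NULL

  aliases <- unique(data.frame(organism = al_org, alias = al_alias,
                               accession = al_acc, stringsAsFactors = FALSE))
  aliases <- aliases[order(aliases$organism, aliases$alias), , drop = FALSE]
  rownames(aliases) <- NULL

  # term table: vocabulary terms plus ad-hoc FT terms (dedup; canonical label
  # for an ad-hoc id is the lexicographically smallest observed spelling, so
  # the result does not depend on record order)
  terms <- rbind(
    data.frame(term_id = vocab$kw$term_id, label = vocab$kw$label, level = "KW",
               stringsAsFactors = FALSE),
    data.frame(term_id = vocab$ft$term_id, label = vocab$ft$label, level = "FT",
               stringsAsFactors = FALSE)
  )
  if (length(adhoc_id)) {
    ad <- data.frame(term_id = adhoc_id, label = adhoc_label,
                     stringsAsFactors = FALSE)
    ad <- ad[order(ad$term_id, ad$label), , drop = FALSE]
    ad <- ad[!duplicated(ad$term_id), , drop = FALSE]
    ad <- ad[!ad$term_id %in% terms$term_id, , drop = FALSE]
    if (nrow(ad)) {
      terms <- rbind(terms, data.frame(term_id = ad$term_id, label = ad$label,
                                       level = "FT", stringsAsFactors = FALSE))
      if (!UNCATEGORIZED_ID %in% terms$term_id) {
        terms <- rbind(terms, data.frame(term_id = UNCATEGORIZED_ID,
                                         label = "Uncategorized", level = "KW",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  terms <- terms[order(terms$level, terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL

  idx_df <- unique(data.frame(organism = ti_org, term_id = ti_term,
                              accession = ti_acc, stringsAsFactors = FALSE))
  idx_df <- idx_df[order(idx_df$organism, idx_df$term_id, idx_df$accession), ,
                   drop = FALSE]
  rownames(idx_df) <- NULL
  term_index <- lapply(split(idx_df, idx_df$organism),
                       function(d) lapply(split(d$accession, d$term_id), sort))

  evidence <- unique(data.frame(organism = ev_org, accession = ev_acc,
                                term_id = ev_term, qualifier = ev_qual,
                                stringsAsFactors = FALSE))
  evidence <- evidence[order(evidence$organism, evidence$accession,
                             evidence$term_id, evidence$qualifier), , drop = FALSE]
  rownames(evidence) <- NULL

  ftkeys <- unique(data.frame(organism = fk_org, accession = fk_acc,
                              key = fk_key, stringsAsFactors = FALSE))
  ftkeys <- ftkeys[order(ftkeys$organism, ftkeys$accession, ftkeys$key), ,
                   drop = FALSE]
  rownames(ftkeys) <- NULL

  db <- structure(
    list(organisms = sort(unique(proteins$organism)),
         proteins = proteins, aliases = aliases, terms = terms,
         term_index = term_index, evidence = evidence,
         ft_key_presence = ftkeys,
         params = list(ft_keys = sort(ft_keys))),
    class = "ptm_database"
  )
  db$fingerprint <- db_fingerprint(db)
  validate_database(db)
  db
}

db_fingerprint <- function(db) {
  md5_of_lines(c(
    paste(db$proteins$organism, db$proteins$accession, db$proteins$source_tag,
          sep = "\t"),
    paste(db$terms$term_id, db$terms$label, db$terms$level, sep = "\t"),
    paste(db$params$ft_keys, collapse = ",")
  ))
}

validate_database <- function(db) {
  key <- paste(db$proteins$organism, db$proteins$accession)
  if (anyDuplicated(key)) {
    ptm_error("accession indexed in more than one partition row", "ptmenrich_db_error")
  }
  for (org in names(db$term_index)) {
    pool <- db$proteins$accession[db$proteins$organism == org]
    for (accs in db$term_index[[org]]) {
      if (!all(accs %in% pool)) {
        ptm_error("term index contains accession outside its organism partition",
                  "ptmenrich_db_error")
      }
    }
  }
  invisible(db)
}

#' @export
print.ptm_database <- function(x, ...) {
  cat(sprintf("<ptm_database> %d protein(s) across %d organism(s); %d term(s); ft_keys = %s\n",
              nrow(x$proteins), length(x$organisms), nrow(x$terms),
              paste(x$params$ft_keys, collapse = ",")))
  invisible(x)
}

organism_size <- function(db, organism) {
  sum(db$proteins$organism == organism)
}

check_organism <- function(db, organism) {
  if (!organism %in% db$organisms) {
    near <- utils::head(db$organisms[utils::adist(tolower(organism),
                                                  tolower(db$organisms)) <=
                                       max(3L, nchar(organism) %/% 3L)], 5L)
    hint <- if (length(near)) paste0("; nearest matches: ",
                                     paste(near, collapse = ", ")) else ""
    ptm_error(sprintf("unknown organism '%s'%s", organism, hint),
              "ptmenrich_db_error")
  }
  invisible(organism)
}

#' Annotation-source Venn counts
#'
#' Partitions every database protein by where its PTM annotation was found:
#' keywords only, feature table only, or both fields.
#'
#' @param db A `ptm_database`.
#' @return A [venn_counts] object.
#' @export
annotation_source_partition <- function(db) {
  tag <- db$proteins$source_tag
  venn_counts(kw_only = sum(tag == "KW-only"),
              ft_only = sum(tag == "FT-only"),
              both = sum(tag == "Both"))
}

#' Venn counts of annotation sources
#'
#' @param kw_only,ft_only,both Non-negative integer counts.
#' @return A list of class `venn_counts` with the three parts and their
#'   `total`.
#' @export
venn_counts <- function(kw_only, ft_only, both) {
  for (v in list(kw_only, ft_only, both)) {
    if (!is_count(v)) ptm_error("venn counts must be non-negative integers",
                                "ptmenrich_param_error")
  }
  structure(list(kw_only = kw_only, ft_only = ft_only, both = both,
                 total = kw_only + ft_only + both),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  p <- venn_percent(x)
  cat(sprintf("<venn_counts> KW-only %d (%d%%), FT-only %d (%d%%), Both %d (%d%%); total %d\n",
              x$kw_only, p[["kw_only"]], x$ft_only, p[["ft_only"]],
              x$both, p[["both"]], x$total))
  invisible(x)
}

#' Venn parts as nearest-integer percentages of the total
#'
#' @param v A [venn_counts] object.
#' @return Named numeric vector `kw_only`, `ft_only`, `both` (percent).
#' @export
venn_percent <- function(v) {
  if (v$total == 0L) {
    return(c(kw_only = 0, ft_only = 0, both = 0))
  }
  round(100 * c(kw_only = v$kw_only, ft_only = v$ft_only, both = v$both) / v$total)
}

#' Percent split of a vector of counts
#'
#' Shared reporting convention for composition charts: each count as a
#' percentage of the sum of all counts, rounded to 2 decimals; all-zero
#' input reports zeros.
#'
#' @param counts Named or unnamed non-negative numeric vector.
#' @return Numeric vector of percentages, same names as `counts`.
#' @export
composition_percent <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(counts * 0)
  round(100 * counts / total, 2)
}

#' Feature-key composition of the FT-derived annotations
#'
#' Among proteins with any feature-derived PTM annotation, counts the
#' proteins having at least one feature of each mined key. A protein with
#' two keys contributes to both counts and twice to the denominator
#' (per-annotation-class composition).
#'
#' @param db A `ptm_database`.
#' @return `data.frame` with columns `key`, `count`, `percent`.
#' @export
ft_key_composition <- function(db) {
  keys <- db$params$ft_keys
  counts <- vapply(keys, function(k) sum(db$ft_key_presence$key == k), integer(1))
  data.frame(key = keys, count = unname(counts),
             percent = unname(composition_percent(counts)),
             stringsAsFactors = FALSE)
}

#' Term frequencies in the database
#'
#' @param db A `ptm_database`.
#' @param organism An organism key, or `"ALL"` for the union-sum across
#'   organisms.
#' @return `data.frame` with `term_id`, `label`, `count`, ordered by
#'   descending count then label.
#' @export
term_frequencies <- function(db, organism = "ALL") {
  idx <- if (identical(organism, "ALL")) {
    db$term_index
  } else {
    check_organism(db, organism)
    db$term_index[organism]
  }
  counts <- list()
  for (org_idx in idx) {
    for (t in names(org_idx)) {
      counts[[t]] <- (counts[[t]] %||% 0L) + length(org_idx[[t]])
    }
  }
  if (length(counts) == 0L) {
    return(data.frame(term_id = character(), label = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(term_id = names(counts),
                    count = as.integer(unlist(counts)),
                    stringsAsFactors = FALSE)
  out$label <- db$terms$label[match(out$term_id, db$terms$term_id)]
  out <- out[order(-out$count, out$label), c("term_id", "label", "count")]
  rownames(out) <- NULL
  out
}

#' Experimental / putative evidence dictionaries
#'
#' Counts, per FT-level term, the proteins whose annotation carries each
#' evidence qualifier; a protein counts once per (term, qualifier) pair, and
#' the `total` dictionary merges both qualifiers.
#'
#' @param db A `ptm_database`.
#' @param organism Organism key or `"ALL"`.
#' @return List of three `data.frame`s (`experimental`, `putative`, `total`)
#'   with `term_id`, `label`, `count`, each sorted by descending count then
#'   label (take `head(x, k)` for top-k).
#' @export
evidence_dictionaries <- function(db, organism = "ALL") {
  ev <- db$evidence
  if (!identical(organism, "ALL")) {
    check_organism(db, organism)
    ev <- ev[ev$organism == organism, , drop = FALSE]
  }
  tab <- function(d) {
    if (nrow(d) == 0L) {
      return(data.frame(term_id = character(), label = character(),
                        count = integer(), stringsAsFactors = FALSE))
    }
    cnt <- table(d$term_id)
    out <- data.frame(term_id = names(cnt), count = as.integer(cnt),
                      stringsAsFactors = FALSE)
    out$label <- db$terms$label[match(out$term_id, db$terms$term_id)]
    out <- out[order(-out$count, out$label), c("term_id", "label", "count")]
    rownames(out) <- NULL
    out
  }
  list(experimental = tab(ev[ev$qualifier == "Experimental", , drop = FALSE]),
       putative = tab(ev[ev$qualifier == "Putative", , drop = FALSE]),
       total = tab(ev))
}

#' Resolve raw protein identifiers within an organism partition
#'
#' Identifiers match by primary accession, secondary accession or entry
#' name, case-insensitively. Blank lines and `#` comment lines are dropped;
#' duplicates collapse to the first occurrence; output order is stable.
#'
#' @param db A `ptm_database`.
#' @param organism Organism key.
#' @param raw_ids Character vector of identifiers as supplied by the user.
#' @return List with `matched` (primary accessions) and `unmatched` (input
#'   ids that resolved to nothing).
#' @export
resolve_proteins <- function(db, organism, raw_ids) {
  check_organism(db, organism)
  ids <- trimws(as.character(raw_ids))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0L) {
    ptm_error("no identifiers left after cleaning the input list",
              "ptmenrich_resolve_error")
  }
  al <- db$aliases[db$aliases$organism == organism, , drop = FALSE]
  hit <- match(tolower(ids), al$alias)
  acc <- al$accession[hit]
  matched <- unique(acc[!is.na(acc)])
  unmatched <- unique(ids[is.na(hit)])
  if (length(matched) == 0L) {
    ptm_error(sprintf(
      "none of the %d identifier(s) matched organism '%s'; check that the organism is correct",
      length(ids), organism), "ptmenrich_resolve_error")
  }
  list(matched = matched, unmatched = unmatched)
}

#' Persist / load a PTM database as a portable plain-text archive
#'
#' The archive is a directory of tab-delimited tables plus a manifest
#' recording the build parameters and a content hash; rebuilding identical
#' input yields a bit-identical archive.
#'
#' @param db A `ptm_database`.
#' @param dir Directory path (created if needed).
#' @return `write_database` returns `dir` invisibly; `read_database` returns
#'   the `ptm_database`.
#' @export
write_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(db$proteins, "proteins.tsv")
  wt(db$aliases, "aliases.tsv")
  wt(db$terms, "terms.tsv")
  idx <- do.call(rbind, lapply(names(db$term_index), function(org) {
    oi <- db$term_index[[org]]
    do.call(rbind, lapply(names(oi), function(t) {
      data.frame(organism = org, term_id = t, accession = oi[[t]],
                 stringsAsFactors = FALSE)
    }))
  })) %||% data.frame(organism = character(), term_id = character(),
                      accession = character())
  wt(idx, "term_index.tsv")
  wt(db$evidence, "evidence.tsv")
  wt(db$ft_key_presence, "ft_key_presence.tsv")
  manifest <- data.frame(
    format_version = "1", ft_keys = paste(db$params$ft_keys, collapse = ","),
    n_proteins = nrow(db$proteins), n_organisms = length(db$organisms),
    fingerprint = db$fingerprint, stringsAsFactors = FALSE
  )
  write.dcf(manifest, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @rdname write_database
#' @export
read_database <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                                      quote = "", colClasses = "character")
  manifest <- as.data.frame(read.dcf(file.path(dir, "MANIFEST")),
                            stringsAsFactors = FALSE)
  proteins <- rt("proteins.tsv")
  proteins$markers[is.na(proteins$markers)] <- ""
  idx <- rt("term_index.tsv")
  term_index <- lapply(split(idx, idx$organism),
                       function(d) lapply(split(d$accession, d$term_id), sort))
  db <- structure(
    list(organisms = sort(unique(proteins$organism)),
         proteins = proteins, aliases = rt("aliases.tsv"), terms = rt("terms.tsv"),
         term_index = term_index, evidence = rt("evidence.tsv"),
         ft_key_presence = rt("ft_key_presence.tsv"),
         params = list(ft_keys = strsplit(manifest$ft_keys, ",")[[1L]])),
    class = "ptm_database"
  )
  db$fingerprint <- manifest$fingerprint
  validate_database(db)
  db
}
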