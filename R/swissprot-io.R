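# Swiss-Prot flat-file (DAT) reading and writing.
#
# Line codes handled: ID, AC, OS, KW, FT, DR, CC; SQ and raw sequence lines
# are tolerated and skipped. Entries end at a "//" line. Two feature-table
# dialects are supported: the classic layout (positions in columns on the FT
# line, description following on the same/continuation lines) and the modern
# post-2019 layout ("begin..end" plus /note="..." qualifiers).

#' Construct a protein record
#'
#' A `protein_record` holds the fields of one Swiss-Prot entry that matter
#' for PTM curation: identifiers, organism, keywords, the feature table and
#' database cross-references. Comment (CC) topics are retained verbatim but
#' are never mined for PTM terms.
#'
#' @param entry_name Entry name token from the ID line (e.g. `"KINA_HUMAN"`).
#' @param accessions Character vector of accession numbers, primary first.
#' @param organism_names Character vector of organism description strings
#'   (one per OS statement; the first is the record's organism).
#' @param keywords Character vector of keywords (no trailing punctuation).
#' @param features `data.frame` with columns `key`, `begin`, `end`,
#'   `description`; positions are integers or `NA` for unknown/ambiguous
#'   markers such as `"?"` or `"<1"`.
#' @param cross_refs `data.frame` with columns `database`, `id`.
#' @param comment_topics `data.frame` with columns `topic`, `text`.
#' @param review_status `"Reviewed"` or `"Unreviewed"`.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(entry_name,
                           accessions,
                           organism_names = character(),
                           keywords = character(),
                           features = empty_features(),
                           cross_refs = empty_cross_refs(),
                           comment_topics = empty_comment_topics(),
                           review_status = "Reviewed") {
  accessions <- as.character(accessions)
  if (length(accessions) == 0L || anyNA(accessions) || !all(nzchar(accessions))) {
    ptm_error("protein_record: accessions must be non-empty", "ptmenrich_record_error")
  }
  if (anyDuplicated(accessions)) {
    ptm_error("protein_record: accessions must be unique within a record",
              "ptmenrich_record_error")
  }
  if (!review_status %in% c("Reviewed", "Unreviewed")) {
    ptm_error("protein_record: review_status must be Reviewed or Unreviewed",
              "ptmenrich_record_error")
  }
  features <- as_features(features)
  bad <- !is.na(features$begin) & !is.na(features$end) & features$begin > features$end
  if (any(bad)) {
    ptm_error("protein_record: feature begin must be <= end", "ptmenrich_record_error")
  }
  if (any(nchar(features$key) > 8L | features$key != toupper(features$key))) {
    ptm_error("protein_record: feature keys are uppercase tokens of <= 8 characters",
              "ptmenrich_record_error")
  }
  structure(
    list(
      entry_name = as.character(entry_name),
      review_status = review_status,
      accessions = accessions,
      organism_names = as.character(organism_names),
      organism_key = organism_key(organism_names),
      keywords = as.character(keywords),
      features = features,
      cross_refs = as_cross_refs(cross_refs),
      comment_topics = as_comment_topics(comment_topics)
    ),
    class = "protein_record"
  )
}

empty_features <- function() {
  data.frame(key = character(), begin = integer(), end = integer(),
             description = character(), stringsAsFactors = FALSE)
}
empty_cross_refs <- function() {
  data.frame(database = character(), id = character(), stringsAsFactors = FALSE)
}
empty_comment_topics <- function() {
  data.frame(topic = character(), text = character(), stringsAsFactors = FALSE)
}

as_features <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty_features())
  data.frame(key = as.character(x$key),
             begin = as.integer(x$begin), end = as.integer(x$end),
             description = as.character(x$description),
             stringsAsFactors = FALSE)
}
as_cross_refs <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty_cross_refs())
  data.frame(database = as.character(x$database), id = as.character(x$id),
             stringsAsFactors = FALSE)
}
as_comment_topics <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(empty_comment_topics())
  data.frame(topic = as.character(x$topic), text = as.character(x$text),
             stringsAsFactors = FALSE)
}

# Canonical organism key: first OS statement up to the first "(", with the
# trailing period dropped and whitespace normalised.
organism_key <- function(organism_names) {
  if (length(organism_names) == 0L) return(NA_character_)
  s <- organism_names[[1L]]
  s <- sub("\\(.*$", "", s)
  s <- sub("\\.\\s*$", "", s)
  collapse_ws(s)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s) [%s]\n", x$entry_name,
              paste(x$accessions, collapse = ", "), x$review_status))
  cat(sprintf("  organism: %s | %d keyword(s), %d feature(s), %d cross-ref(s)\n",
              x$organism_key, length(x$keywords), nrow(x$features),
              nrow(x$cross_refs)))
  invisible(x)
}

pos_token_parse <- function(tok) {
  tok <- sub("^[<>]", "", tok)
  if (grepl("^[0-9]+$", tok)) as.integer(tok) else NA_integer_
}

pos_token_format <- function(p) if (is.na(p)) "?" else as.character(p)

#' Detect the feature-table dialect of DAT lines
#'
#' Returns `"modern"` if any FT line uses the `begin..end` position syntax or
#' a `/note=` qualifier, `"classic"` otherwise (including when no FT lines
#' are present). A mix of both dialects in one stream is an error.
#'
#' @param lines Character vector of raw DAT lines.
#' @return `"classic"` or `"modern"`.
#' @export
detect_dialect <- function(lines) {
  ft <- lines[startsWith(lines, "FT   ")]
  if (length(ft) == 0L) return("classic")
  content <- substring(ft, 6L)
  modern <- grepl("[0-9?<>]+\\.\\.[0-9?<>]+", content) |
    grepl("/note=", content, fixed = TRUE) |
    (grepl("^\\s+/", content) & !grepl("/FTId", content, fixed = TRUE))
  classic <- logical(length(ft))
  keyline <- !grepl("^\\s", content)
  for (i in which(keyline & !modern)) {
    toks <- strsplit(trimws(content[i]), "[[:space:]]+")[[1L]]
    if (length(toks) >= 3L &&
        grepl("^[<>?]?[0-9?]+$", toks[2L]) && grepl("^[<>?]?[0-9?]+$", toks[3L])) {
      classic[i] <- TRUE
    }
  }
  has_modern <- any(modern)
  has_classic <- any(classic)
  if (has_modern && has_classic) {
    ptm_error("mixed classic and modern FT dialects in one stream",
              "ptmenrich_parse_error")
  }
  if (has_modern) "modern" else "classic"
}

# Parse the accumulated lines of a single entry.
parse_one_entry <- function(lines, start_line, dialect) {
  idl <- which(startsWith(lines, "ID   "))
  if (length(idl) == 0L) {
    ptm_error(sprintf("entry starting at line %d has no ID line before '//'",
                      start_line),
              "ptmenrich_parse_error", line = start_line)
  }
  id_content <- trimws(substring(lines[idl[1L]], 6L))
  id_toks <- strsplit(id_content, "[[:space:]]+")[[1L]]
  entry_name <- id_toks[1L]
  review <- if (any(grepl("Unreviewed", id_toks))) "Unreviewed" else "Reviewed"

  content_of <- function(code) substring(lines[startsWith(lines, paste0(code, "   "))], 6L)

  # AC: merged in order, split on ";"
  ac <- unlist(strsplit(paste(content_of("AC"), collapse = " "), ";"))
  ac <- trimws(ac)
  ac <- ac[nzchar(ac)]

  # OS: a name ends at a line whose content ends with "."; continuations join
  os_lines <- content_of("OS")
  organism_names <- character()
  pending <- character()
  for (s in os_lines) {
    pending <- c(pending, trimws(s))
    if (grepl("\\.\\s*$", s)) {
      nm <- collapse_ws(paste(pending, collapse = " "))
      organism_names <- c(organism_names, sub("\\.$", "", nm))
      pending <- character()
    }
  }
  if (length(pending)) {
    organism_names <- c(organism_names, collapse_ws(paste(pending, collapse = " ")))
  }

  # KW: concatenated, trailing "." stripped, split on ";"
  kw_all <- collapse_ws(paste(content_of("KW"), collapse = " "))
  kw_all <- sub("\\.$", "", kw_all)
  keywords <- trimws(unlist(strsplit(kw_all, ";")))
  keywords <- keywords[nzchar(keywords)]

  # DR: "Database; id; ...."
  dr_lines <- content_of("DR")
  cross_refs <- empty_cross_refs()
  if (length(dr_lines)) {
    parts <- strsplit(dr_lines, ";")
    cross_refs <- data.frame(
      database = vapply(parts, function(p) trimws(p[1L]), character(1)),
      id = vapply(parts, function(p) {
        if (length(p) >= 2L) sub("\\.$", "", trimws(p[2L])) else ""
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  # CC: "-!- TOPIC: text" with plain continuation lines; retained verbatim
  cc_lines <- content_of("CC")
  topics <- character(); texts <- character()
  for (s in cc_lines) {
    if (startsWith(s, "-!-")) {
      rest <- trimws(substring(s, 4L))
      colon <- regexpr(":", rest, fixed = TRUE)
      if (colon > 0L) {
        topics <- c(topics, trimws(substr(rest, 1L, colon - 1L)))
        texts <- c(texts, trimws(substring(rest, colon + 1L)))
      } else {
        topics <- c(topics, rest)
        texts <- c(texts, "")
      }
    } else if (length(topics)) {
      texts[length(texts)] <- collapse_ws(paste(texts[length(texts)], trimws(s)))
    }
  }
  comment_topics <- if (length(topics)) {
    data.frame(topic = topics, text = texts, stringsAsFactors = FALSE)
  } else empty_comment_topics()

  ft_lines <- content_of("FT")
  features <- if (identical(dialect, "modern")) {
    parse_ft_modern(ft_lines)
  } else {
    parse_ft_classic(ft_lines)
  }

  protein_record(
    entry_name = entry_name, accessions = ac,
    organism_names = organism_names, keywords = keywords,
    features = features, cross_refs = cross_refs,
    comment_topics = comment_topics, review_status = review
  )
}

parse_ft_classic <- function(content) {
  keys <- character(); begins <- integer(); ends <- integer(); descs <- character()
  for (s in content) {
    if (!grepl("^\\s", s)) {
      toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
      if (length(toks) < 3L) {
        ptm_error(sprintf("malformed classic FT line: '%s'", s), "ptmenrich_parse_error")
      }
      keys <- c(keys, toks[1L])
      begins <- c(begins, pos_token_parse(toks[2L]))
      ends <- c(ends, pos_token_parse(toks[3L]))
      descs <- c(descs, paste(toks[-(1:3)], collapse = " "))
    } else if (length(keys)) {
      cont <- trimws(s)
      if (startsWith(cont, "/")) next  # /FTId and similar qualifiers
      i <- length(descs)
      descs[i] <- trimws(paste(descs[i], cont))
    }
  }
  descs <- sub("\\.$", "", trimws(descs))
  data.frame(key = keys, begin = begins, end = ends, description = descs,
             stringsAsFactors = FALSE)
}

parse_ft_modern <- function(content) {
  keys <- character(); begins <- integer(); ends <- integer(); descs <- character()
  in_note <- FALSE
  for (s in content) {
    if (!grepl("^\\s", s)) {
      toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
      if (length(toks) < 2L) {
        ptm_error(sprintf("malformed modern FT line: '%s'", s), "ptmenrich_parse_error")
      }
      pos <- strsplit(toks[2L], "..", fixed = TRUE)[[1L]]
      keys <- c(keys, toks[1L])
      begins <- c(begins, pos_token_parse(pos[1L]))
      ends <- c(ends, pos_token_parse(if (length(pos) > 1L) pos[2L] else pos[1L]))
      descs <- c(descs, "")
      in_note <- FALSE
    } else if (length(keys)) {
      cont <- trimws(s)
      i <- length(descs)
      if (startsWith(cont, "/note=\"")) {
        txt <- substring(cont, 8L)
        if (grepl("\"$", txt)) {
          descs[i] <- sub("\"$", "", txt)
          in_note <- FALSE
        } else {
          descs[i] <- txt
          in_note <- TRUE
        }
      } else if (in_note) {
        if (grepl("\"$", cont)) {
          descs[i] <- paste(descs[i], sub("\"$", "", cont))
          in_note <- FALSE
        } else {
          descs[i] <- paste(descs[i], cont)
        }
      }
      # other qualifiers (/evidence=, /id=) are ignored
    }
  }
  descs <- sub("\\.$", "", trimws(descs))
  data.frame(key = keys, begin = begins, end = ends, description = descs,
             stringsAsFactors = FALSE)
}

#' Parse Swiss-Prot flat-file entries
#'
#' Streams a DAT-format text and yields one [protein_record] per entry
#' (entries are delimited by `//` lines). Input is treated as UTF-8 with a
#' per-line Latin-1 fallback. When `callback` is supplied the function works
#' through the stream in line chunks, invoking `callback(record)` for each
#' entry and keeping only one entry's lines in memory, so arbitrarily large
#' files can be processed; otherwise all records are returned as a list.
#'
#' @param x A file path, a connection, or a character vector of lines (a
#'   single string containing newlines is split).
#' @param dialect `"classic"`, `"modern"`, or `NULL` to auto-detect from the
#'   first chunk of lines (see [detect_dialect]).
#' @param callback Optional function of one argument called with each parsed
#'   record; when given, `parse_entries` returns the number of entries
#'   processed instead of the records.
#' @return A list of `protein_record` objects, or the entry count when
#'   `callback` is used.
#' @export
parse_entries <- function(x, dialect = NULL, callback = NULL) {
  close_con <- FALSE
  if (inherits(x, "connection")) {
    con <- x
  } else if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    con <- file(x, open = "r")
    close_con <- TRUE
  } else {
    if (is.character(x) && any(grepl("\n", x))) {
      x <- unlist(strsplit(x, "\n", fixed = TRUE))
    }
    con <- textConnection(x)
    close_con <- TRUE
  }
  if (close_con) on.exit(close(con))

  records <- if (is.null(callback)) vector("list", 0L) else NULL
  n_rec <- 0L
  entry_lines <- character()
  entry_start <- 1L
  line_no <- 0L
  first_chunk <- TRUE

  repeat {
    chunk <- readLines(con, n = 4096L, warn = FALSE)
    if (length(chunk) == 0L) break
    bad <- !validUTF8(chunk)
    if (any(bad)) chunk[bad] <- iconv(chunk[bad], "latin1", "UTF-8")
    if (first_chunk && is.null(dialect)) dialect <- detect_dialect(chunk)
    first_chunk <- FALSE
    for (ln in chunk) {
      line_no <- line_no + 1L
      if (identical(trimws(ln), "//")) {
        rec <- parse_one_entry(entry_lines, entry_start, dialect)
        n_rec <- n_rec + 1L
        if (is.null(callback)) records[[n_rec]] <- rec else callback(rec)
        entry_lines <- character()
        entry_start <- line_no + 1L
      } else {
        entry_lines <- c(entry_lines, ln)
      }
    }
  }
  if (any(nzchar(trimws(entry_lines)))) {
    idl <- entry_lines[startsWith(entry_lines, "ID   ")]
    last_name <- if (length(idl)) {
      strsplit(trimws(substring(idl[1L], 6L)), "[[:space:]]+")[[1L]][1L]
    } else if (n_rec > 0L && is.null(callback)) {
      records[[n_rec]]$entry_name
    } else "<unknown>"
    ptm_error(sprintf("truncated final entry (EOF before '//'); last entry seen: %s",
                      last_name),
              "ptmenrich_parse_error", entry_name = last_name)
  }
  if (is.null(callback)) records else n_rec
}

wrap_items <- function(code, items, sep = "; ", terminal = ".", width = 75L) {
  if (length(items) == 0L) return(character())
  pieces <- paste0(items, c(rep(";", length(items) - 1L), terminal))
  lines <- character(); cur <- ""
  for (p in pieces) {
    cand <- if (nzchar(cur)) paste(cur, p) else p
    if (nzchar(cur) && nchar(cand) > width) {
      lines <- c(lines, cur)
      cur <- p
    } else cur <- cand
  }
  lines <- c(lines, cur)
  paste0(code, "   ", lines)
}

#' Write a protein record as Swiss-Prot flat-file text
#'
#' Produces DAT text whose re-parse reproduces the record field for field
#' (round-trip identity), in either feature-table dialect. Feature
#' descriptions are written with a terminal period in the classic dialect and
#' as `/note` qualifiers in the modern one; descriptions must not contain
#' line terminators.
#'
#' @param record A [protein_record].
#' @param dialect `"classic"` (default) or `"modern"`.
#' @return A single string of DAT text ending with the `//` terminator line.
#' @seealso [write_entries] for whole files.
#' @export
write_entry <- function(record, dialect = c("classic", "modern")) {
  dialect <- match.arg(dialect)
  txt_fields <- c(record$entry_name, record$accessions, record$organism_names,
                  record$keywords, record$features$description,
                  record$cross_refs$database, record$cross_refs$id,
                  record$comment_topics$topic, record$comment_topics$text)
  if (any(grepl("[\r\n]", txt_fields))) {
    ptm_error("write_entry: fields must not contain line terminators",
              "ptmenrich_write_error")
  }
  out <- sprintf("ID   %-18s %s;%12d AA.", record$entry_name,
                 record$review_status, 100L)
  out <- c(out, wrap_items("AC", record$accessions, terminal = ";"))
  out <- c(out, sprintf("OS   %s.", record$organism_names))
  out <- c(out, wrap_items("KW", record$keywords))
  f <- record$features
  if (nrow(f)) {
    if (dialect == "classic") {
      for (i in seq_len(nrow(f))) {
        base <- sprintf("FT   %-8s %6s %6s", f$key[i],
                        pos_token_format(f$begin[i]), pos_token_format(f$end[i]))
        d <- f$description[i]
        out <- c(out, if (nzchar(d)) paste0(base, "       ", d, ".") else base)
      }
    } else {
      for (i in seq_len(nrow(f))) {
        b <- pos_token_format(f$begin[i]); e <- pos_token_format(f$end[i])
        pos <- if (identical(b, e)) b else paste0(b, "..", e)
        out <- c(out, sprintf("FT   %-15s %s", f$key[i], pos))
        if (nzchar(f$description[i])) {
          out <- c(out, sprintf("FT                   /note=\"%s\"", f$description[i]))
        }
      }
    }
  }
  dr <- record$cross_refs
  if (nrow(dr)) out <- c(out, sprintf("DR   %s; %s; -.", dr$database, dr$id))
  cc <- record$comment_topics
  if (nrow(cc)) out <- c(out, sprintf("CC   -!- %s: %s", cc$topic, cc$text))
  out <- c(out, "//")
  paste(out, collapse = "\n")
}

#' Write multiple records, optionally to a file
#'
#' @param records List of [protein_record] objects.
#' @param dialect Feature-table dialect passed to [write_entry].
#' @param path Optional file path; when given the text is written there.
#' @return The DAT text as a single string (invisibly when `path` is given).
#' @export
write_entries <- function(records, dialect = c("classic", "modern"), path = NULL) {
  dialect <- match.arg(dialect)
  txt <- paste(vapply(records, write_entry, character(1), dialect = dialect),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
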