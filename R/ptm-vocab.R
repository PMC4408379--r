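# The controlled PTM vocabulary and its three-level DAG.
#
# Level 0 is the literal root "PTM"; level 1 holds keyword-level (KW) terms;
# level 2 holds feature-level (FT) terms. Every FT term has >= 1 KW parent
# (multiple parents make this a DAG rather than a tree); every KW term's only
# parent is the root.

PUTATIVE_QUALIFIERS <- c("By similarity", "Probable", "Potential")

#' Load a PTM vocabulary
#'
#' @param kw_terms Character vector of keyword-level term labels.
#' @param ft_terms Character vector of feature-level term labels.
#' @param edges `data.frame` with columns `ft` and `kw` giving, for each
#'   FT-level label, one of its KW-level parents. Every FT term must appear
#'   in at least one edge.
#' @return A `ptm_vocabulary`: indexed term tables plus the FT-to-KW edge
#'   set, supporting case-insensitive label lookup per level.
#' @export
load_vocabulary <- function(kw_terms, ft_terms = character(), edges = NULL) {
  kw_terms <- as.character(kw_terms)
  ft_terms <- as.character(ft_terms)
  dup_check <- function(labels, level) {
    d <- unique(labels[duplicated(tolower(labels))])
    if (length(d)) {
      ptm_error(sprintf("duplicate %s-level label(s): %s", level,
                        paste(d, collapse = ", ")),
                "ptmenrich_vocab_error")
    }
  }
  dup_check(kw_terms, "KW")
  dup_check(ft_terms, "FT")

  if (is.null(edges)) {
    edges <- data.frame(ft = character(), kw = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(ft = as.character(edges$ft), kw = as.character(edges$kw),
                      stringsAsFactors = FALSE)
  bad_ft <- edges$ft[!tolower(edges$ft) %in% tolower(ft_terms)]
  bad_kw <- edges$kw[!tolower(edges$kw) %in% tolower(kw_terms)]
  if (length(bad_ft) || length(bad_kw)) {
    ptm_error(sprintf("edges reference unknown label(s): %s",
                      paste(unique(c(bad_ft, bad_kw)), collapse = ", ")),
              "ptmenrich_vocab_error")
  }
  orphan <- setdiff(tolower(ft_terms), tolower(edges$ft))
  if (length(orphan)) {
    ptm_error(sprintf("FT term(s) without a KW parent: %s",
                      paste(ft_terms[tolower(ft_terms) %in% orphan], collapse = ", ")),
              "ptmenrich_vocab_error")
  }

  kw <- data.frame(term_id = make.unique(slugify(kw_terms), sep = "-"),
                   label = kw_terms, stringsAsFactors = FALSE)
  ft_ids <- if (length(ft_terms)) {
    make.unique(paste0("ft-", slugify(ft_terms)), sep = "-")
  } else character()
  ft <- data.frame(term_id = ft_ids, label = ft_terms, stringsAsFactors = FALSE)
  edge_ids <- unique(data.frame(
    ft_id = ft$term_id[match(tolower(edges$ft), tolower(ft$label))],
    kw_id = kw$term_id[match(tolower(edges$kw), tolower(kw$label))],
    stringsAsFactors = FALSE
  ))
  edge_ids <- edge_ids[order(edge_ids$ft_id, edge_ids$kw_id), , drop = FALSE]
  rownames(edge_ids) <- NULL
  structure(list(kw = kw, ft = ft, edges = edge_ids), class = "ptm_vocabulary")
}

#' @export
print.ptm_vocabulary <- function(x, ...) {
  cat(sprintf("<ptm_vocabulary> %d KW term(s), %d FT term(s), %d edge(s)\n",
              nrow(x$kw), nrow(x$ft), nrow(x$edges)))
  invisible(x)
}

# case-insensitive label -> term_id within a level; NA when absent
vocab_lookup <- function(vocab, labels, level = c("KW", "FT")) {
  level <- match.arg(level)
  tab <- if (level == "KW") vocab$kw else vocab$ft
  tab$term_id[match(tolower(labels), tolower(tab$label))]
}

#' Read / write the tab-delimited vocabulary exchange format
#'
#' Columns: `level` (`KW` or `FT`), `label`, `parent_labels`
#' (`|`-separated KW labels; empty for KW terms).
#'
#' @param path File path.
#' @return [read_vocabulary] returns a `ptm_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  kw <- tab$label[tab$level == "KW"]
  ftrows <- tab[tab$level == "FT", , drop = FALSE]
  edges <- NULL
  if (nrow(ftrows)) {
    parents <- strsplit(ftrows$parent_labels, "|", fixed = TRUE)
    edges <- data.frame(
      ft = rep(ftrows$label, lengths(parents)),
      kw = unlist(parents),
      stringsAsFactors = FALSE
    )
  }
  load_vocabulary(kw, ftrows$label, edges)
}

#' @rdname read_vocabulary
#' @param vocab A `ptm_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  parents <- vapply(vocab$ft$term_id, function(id) {
    kw_ids <- vocab$edges$kw_id[vocab$edges$ft_id == id]
    paste(vocab$kw$label[match(kw_ids, vocab$kw$term_id)], collapse = "|")
  }, character(1))
  tab <- rbind(
    data.frame(level = "KW", label = vocab$kw$label, parent_labels = "",
               stringsAsFactors = FALSE),
    data.frame(level = "FT", label = vocab$ft$label, parent_labels = unname(parents),
               stringsAsFactors = FALSE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The vocabulary shipped with the package
#'
#' A small illustrative vocabulary covering well-known keyword-level PTM
#' categories (Phosphoprotein, Glycoprotein, Acetylation, ...) and common
#' feature-level modified-residue terms (Phosphoserine, N6-acetyllysine,
#' ...). Note that "Nucleotide-binding" is included among the keyword terms
#' for compatibility with common PTM curation practice even though it is not
#' itself a covalent modification. Real analyses should supply a complete
#' vocabulary via [read_vocabulary]; the edge set here is illustrative.
#'
#' @return A `ptm_vocabulary`.
#' @export
default_vocabulary <- function() {
  read_vocabulary(system.file("extdata", "ptm_vocabulary.tsv",
                              package = "ptmenrich", mustWork = TRUE))
}

#' Build the three-level PTM DAG from a vocabulary
#'
#' @param vocab A `ptm_vocabulary`.
#' @return A `ptm_dag` with the literal root `"PTM"` at level 0, KW terms at
#'   level 1 and FT terms at level 2. Node count is `1 + |KW| + |FT|`.
#' @export
build_dag <- function(vocab) {
  if (!inherits(vocab, "ptm_vocabulary")) {
    ptm_error("build_dag requires a ptm_vocabulary", "ptmenrich_vocab_error")
  }
  nodes <- rbind(
    data.frame(term_id = "PTM", label = "PTM", level = 0L, stringsAsFactors = FALSE),
    data.frame(term_id = vocab$kw$term_id, label = vocab$kw$label,
               level = rep(1L, nrow(vocab$kw)), stringsAsFactors = FALSE),
    data.frame(term_id = vocab$ft$term_id, label = vocab$ft$label,
               level = rep(2L, nrow(vocab$ft)), stringsAsFactors = FALSE)
  )
  edges <- rbind(
    data.frame(child = vocab$kw$term_id,
               parent = rep("PTM", nrow(vocab$kw)), stringsAsFactors = FALSE),
    data.frame(child = vocab$edges$ft_id, parent = vocab$edges$kw_id,
               stringsAsFactors = FALSE)
  )
  new_ptm_dag(nodes, edges)
}

new_ptm_dag <- function(nodes, edges) {
  nodes <- nodes[order(nodes$level, nodes$term_id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- unique(edges[order(edges$child, edges$parent), , drop = FALSE])
  rownames(edges) <- NULL
  dag <- structure(list(root = "PTM", nodes = nodes, edges = edges),
                   class = "ptm_dag")
  validate_dag(dag)
  dag
}

validate_dag <- function(dag) {
  nodes <- dag$nodes; edges <- dag$edges
  if (sum(nodes$level == 0L) != 1L || nodes$term_id[nodes$level == 0L] != "PTM") {
    ptm_error("DAG must have the single root 'PTM'", "ptmenrich_dag_error")
  }
  if (anyDuplicated(nodes$term_id)) {
    ptm_error("duplicate node ids in DAG", "ptmenrich_dag_error")
  }
  if (!all(nodes$level %in% 0:2)) {
    ptm_error("DAG levels must be 0 (root), 1 (KW) or 2 (FT)", "ptmenrich_dag_error")
  }
  dangling <- setdiff(c(edges$child, edges$parent), nodes$term_id)
  if (length(dangling)) {
    ptm_error(sprintf("edge references unknown node(s): %s",
                      paste(dangling, collapse = ", ")),
              "ptmenrich_dag_error")
  }
  lv <- stats::setNames(nodes$level, nodes$term_id)
  if (any(lv[edges$child] != lv[edges$parent] + 1L)) {
    bad <- edges$child[lv[edges$child] != lv[edges$parent] + 1L][1L]
    ptm_error(sprintf("node '%s' has a parent outside the level above it", bad),
              "ptmenrich_dag_error")
  }
  for (l in 1:2) {
    ids <- nodes$term_id[nodes$level == l]
    no_parent <- setdiff(ids, edges$child)
    if (length(no_parent)) {
      ptm_error(sprintf("node(s) unreachable from root: %s",
                        paste(no_parent, collapse = ", ")),
                "ptmenrich_dag_error")
    }
  }
  # explicit cycle check (levels already forbid cycles; belt and braces for
  # hand-edited XML where levels may have been tampered with)
  parents_of <- split(edges$parent, edges$child)
  seen <- character()
  visit <- function(id, stack) {
    if (id %in% stack) {
      ptm_error(sprintf("cycle detected at node '%s'", id), "ptmenrich_dag_error")
    }
    for (p in parents_of[[id]] %||% character()) visit(p, c(stack, id))
  }
  for (id in nodes$term_id) visit(id, character())
  invisible(dag)
}

#' @export
print.ptm_dag <- function(x, ...) {
  cat(sprintf("<ptm_dag> root 'PTM'; %d KW node(s), %d FT node(s), %d edge(s)\n",
              sum(x$nodes$level == 1L), sum(x$nodes$level == 2L), nrow(x$edges)))
  invisible(x)
}

level_names <- c("root", "KW", "FT")

#' Serialize / read the PTM DAG as XML
#'
#' Schema: `<ptmdag>` containing flat `<term id=.. label=.. level=..>`
#' elements (level one of `root`, `KW`, `FT`), each holding zero or more
#' `<parent ref=..>` children. Flat elements with parent references represent
#' multi-parent nodes without duplication.
#'
#' @param dag A `ptm_dag`.
#' @param path Optional file to write to.
#' @return `dag_to_xml` returns the XML text (invisibly when `path` given);
#'   `dag_from_xml` returns a validated `ptm_dag`.
#' @export
dag_to_xml <- function(dag, path = NULL) {
  doc <- xml2::xml_new_root("ptmdag")
  edges_by_child <- split(dag$edges$parent, dag$edges$child)
  for (i in seq_len(nrow(dag$nodes))) {
    term <- xml2::xml_add_child(doc, "term",
                                id = dag$nodes$term_id[i],
                                label = dag$nodes$label[i],
                                level = level_names[dag$nodes$level[i] + 1L])
    for (p in edges_by_child[[dag$nodes$term_id[i]]] %||% character()) {
      xml2::xml_add_child(term, "parent", ref = p)
    }
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' @rdname dag_to_xml
#' @param x XML text or a path to an XML file.
#' @export
dag_from_xml <- function(x) {
  doc <- if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE) &&
             file.exists(x)) {
    xml2::read_xml(x)
  } else {
    xml2::read_xml(paste(x, collapse = "\n"))
  }
  terms <- xml2::xml_find_all(doc, "/ptmdag/term")
  if (length(terms) == 0L) {
    ptm_error("XML has no /ptmdag/term elements", "ptmenrich_dag_error")
  }
  ids <- xml2::xml_attr(terms, "id")
  labels <- xml2::xml_attr(terms, "label")
  levels <- xml2::xml_attr(terms, "level")
  missing <- is.na(ids) | is.na(labels) | is.na(levels)
  if (any(missing)) {
    who <- ifelse(is.na(ids[missing]), paste0("#", which(missing)), ids[missing])
    ptm_error(sprintf("term element(s) missing id/label/level: %s",
                      paste(who, collapse = ", ")),
              "ptmenrich_dag_error")
  }
  if (!all(levels %in% level_names)) {
    bad <- ids[!levels %in% level_names][1L]
    ptm_error(sprintf("term '%s' has an invalid level", bad), "ptmenrich_dag_error")
  }
  nodes <- data.frame(term_id = ids, label = labels,
                      level = match(levels, level_names) - 1L,
                      stringsAsFactors = FALSE)
  child <- character(); parent <- character()
  for (i in seq_along(terms)) {
    refs <- xml2::xml_attr(xml2::xml_find_all(terms[[i]], "parent"), "ref")
    if (length(refs)) {
      if (anyNA(refs)) {
        ptm_error(sprintf("term '%s' has a parent element without a ref", ids[i]),
                  "ptmenrich_dag_error")
      }
      child <- c(child, rep(ids[i], length(refs)))
      parent <- c(parent, refs)
    }
  }
  new_ptm_dag(nodes, data.frame(child = child, parent = parent,
                                stringsAsFactors = FALSE))
}

#' Normalize a feature description into a vocabulary term and evidence
#'
#' Cleaning rules, applied in order: trailing periods/whitespace stripped;
#' parenthesized evidence qualifiers (`(By similarity)`, `(Probable)`,
#' `(Potential)`, case-insensitive) removed — their presence marks the
#' annotation `Putative`, otherwise `Experimental`; the text truncated at the
#' first `;` (agent clauses such as `"; by PKA"`); whitespace collapsed.
#' Internal parentheses that are part of the term (e.g.
#' `"N6-(pyridoxal phosphate)lysine"`) are preserved. The operation is
#' idempotent.
#'
#' @param raw_text Character vector of raw FT descriptions.
#' @param qualifiers Character vector of qualifier words treated as putative
#'   evidence markers.
#' @return `data.frame` with columns `label` and `qualifier`
#'   (`"Experimental"`/`"Putative"`); an empty description after cleaning
#'   yields `NA` in both columns ("unnamed feature": callers skip it).
#' @export
normalize_ft_description <- function(raw_text, qualifiers = PUTATIVE_QUALIFIERS) {
  s <- trimws(as.character(raw_text))
  s <- sub("[.[:space:]]+$", "", s)
  qre <- paste0("\\(\\s*(", paste(qualifiers, collapse = "|"), ")\\s*\\)")
  putative <- grepl(qre, s, ignore.case = TRUE)
  s <- gsub(qre, "", s, ignore.case = TRUE)
  s <- sub(";.*$", "", s)
  s <- collapse_ws(s)
  s <- sub("[.[:space:]]+$", "", s)
  empty <- !nzchar(s)
  data.frame(
    label = ifelse(empty, NA_character_, s),
    qualifier = ifelse(empty, NA_character_,
                       ifelse(putative, "Putative", "Experimental")),
    stringsAsFactors = FALSE
  )
}
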