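#' Rule-based sentence segmentation
#'
#' Deterministic splitting of plain text on sentence-final punctuation
#' (`.`, `!`, `?` followed by whitespace and an upper-case letter or
#' digit), with an abbreviation guard list and a guard for single-capital
#' initials (`"A."`). Trailing whitespace stays attached to the preceding
#' sentence so that `paste0()` of the segments reconstructs the input
#' exactly.
#'
#' @param text character scalar.
#' @param abbreviations abbreviation forms (with trailing dot) that never
#'   end a sentence.
#' @return character vector of sentences, in order.
#' @export
split_sentences <- function(text,
                            abbreviations = c("e.g.", "i.e.", "cf.", "vs.",
                                              "et al.", "approx.", "Fig.",
                                              "Figs.", "no.", "sp.", "spp.",
                                              "ca.", "cv.")) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (!(chars[i] %in% c(".", "!", "?"))) next
    # must be followed by whitespace then an upper-case letter or digit
    j <- i + 1L
    if (!grepl("[[:space:]]", chars[j])) next
    k <- j
    while (k <= n && grepl("[[:space:]]", chars[k])) k <- k + 1L
    if (k > n || !grepl("[[:upper:][:digit:]]", chars[k])) next
    if (chars[i] == ".") {
      # token ending at i (including the dot)
      start <- i
      while (start > 1L && !grepl("[[:space:]]", chars[start - 1L])) start <- start - 1L
      token <- paste(chars[start:i], collapse = "")
      if (token %in% abbreviations) next
      # "et al." style multiword guards
      prev2 <- paste(chars[max(1L, start - 3L):i], collapse = "")
      if (any(vapply(abbreviations, function(a) endsWith(prev2, a), logical(1)))) next
      # single capital initial, e.g. "A."
      if (grepl("^[A-Z]\\.$", token)) next
    }
    # sentence ends after the trailing whitespace run (so concatenation of
    # segments reproduces the text)
    boundaries <- c(boundaries, k - 1L)
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  vapply(seq_along(starts), function(s)
    paste(chars[starts[s]:ends[s]], collapse = ""), character(1))
}

# whole-token tokenisation: split on non-alphanumeric boundaries but keep
# hyphenated tokens intact
tokenize <- function(text) {
  toks <- strsplit(text, "[^A-Za-z0-9-]+")[[1]]
  toks[nzchar(toks) & toks != "-"]
}

#' Build a term dictionary from concept names
#'
#' One entry per distinct name/synonym of every concept of `class`, keyed
#' by the surface form; entries shorter than `min_len` characters are
#' excluded (short symbols match too promiscuously). A surface form may map
#' to several concepts.
#'
#' @param g a `kg`.
#' @param class concept-class id whose names populate the dictionary.
#' @param min_len minimum surface-form length (default 3).
#' @param case_sensitive logical; gene symbols are case-informative
#'   (`TRUE`), ontology terms usually are not (`FALSE`).
#' @return list of class `gsknet_dictionary`: `entries` (named list,
#'   surface form -> concept ids), `case_sensitive`, `min_len`, `class`.
#' @export
build_dictionary <- function(g, class, min_len = 3, case_sensitive = TRUE) {
  stopifnot(inherits(g, "kg"))
  if (!meta_has(g$meta, "concept_classes", class))
    meta_error("unknown concept class '%s'", class)
  entries <- list()
  for (k in ls(g$concepts)) {
    con <- g$concepts[[k]]
    if (con$class != class) next
    for (nm in con$names$name) {
      if (nchar(nm) < min_len) next
      key <- if (case_sensitive) nm else tolower(nm)
      entries[[key]] <- sort(unique(c(entries[[key]], con$id)))
    }
  }
  structure(list(entries = entries[order(names(entries))],
                 case_sensitive = case_sensitive,
                 min_len = min_len, class = class),
            class = "gsknet_dictionary")
}

#' Export a dictionary as a two-column TSV
#'
#' @param dict a [build_dictionary()] result.
#' @param path destination file (columns: surface form, concept ids
#'   comma-separated).
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  lines <- c("surface\tconcepts",
             vapply(names(dict$entries), function(k)
               paste0(k, "\t", paste(dict$entries[[k]], collapse = ",")),
               character(1)))
  write_lines_lf(lines, path)
  invisible(path)
}

# match dictionary surface forms as whole-token (multi-token) subsequences
# of a tokenised sentence; returns concept ids
match_dictionary <- function(dict, tokens) {
  tk <- if (dict$case_sensitive) tokens else tolower(tokens)
  out <- integer(0)
  for (surface in names(dict$entries)) {
    st <- tokenize(surface)
    if (dict$case_sensitive == FALSE) st <- tolower(st)
    L <- length(st)
    if (L == 0 || L > length(tk)) next
    hit <- FALSE
    if (L == 1) {
      hit <- st %in% tk
    } else {
      for (s in seq_len(length(tk) - L + 1L))
        if (all(tk[s:(s + L - 1L)] == st)) { hit <- TRUE; break }
    }
    if (hit) out <- c(out, dict$entries[[surface]])
  }
  sort(unique(out))
}

#' Same-sentence co-occurrence mapping
#'
#' Scans the `Abstract` attribute of every Publication concept, splits it
#' into sentences, and for each sentence pairs every gene-dictionary match
#' with every term-dictionary match (whole-token matching). Each distinct
#' (gene, term) pair yields one relation of type `cooccurs_with` with
#' text-mining evidence, carrying a `CoCitations` attribute (number of
#' distinct supporting publications) and the supporting `PMIDs`. Pairs
#' whose mentions fall in different sentences are never linked.
#'
#' @param g a `kg` (mutated).
#' @param gene_dict,term_dict [build_dictionary()] dictionaries; typically
#'   gene names (case-sensitive) and trait-ontology terms
#'   (case-insensitive).
#' @param type relation type for the created links.
#' @return number of relations added. The co-mention table (gene, term,
#'   publication, sentence index) is attached as attribute `"comentions"`.
#' @export
cooccurrence_map <- function(g, gene_dict, term_dict, type = "cooccurs_with") {
  stopifnot(inherits(g, "kg"), inherits(gene_dict, "gsknet_dictionary"),
            inherits(term_dict, "gsknet_dictionary"))
  if (length(gene_dict$entries) == 0 || length(term_dict$entries) == 0) {
    warning("empty dictionary; no co-occurrence links created")
    return(0L)
  }
  comentions <- list()
  for (k in ls(g$concepts)) {
    con <- g$concepts[[k]]
    if (con$class != "Publication") next
    abstract <- con$attributes$Abstract
    if (is.null(abstract) || !nzchar(abstract)) next
    pmid <- NA_character_
    for (a in con$accessions) if (a$namespace == "PMID") { pmid <- a$value; break }
    sentences <- split_sentences(abstract)
    for (si in seq_along(sentences)) {
      tokens <- tokenize(sentences[si])
      genes <- match_dictionary(gene_dict, tokens)
      if (length(genes) == 0) next
      terms <- match_dictionary(term_dict, tokens)
      for (ge in genes) for (te in terms) {
        if (ge == te) next
        comentions[[length(comentions) + 1L]] <-
          list(gene = ge, term = te, publication = con$id,
               pmid = pmid, sentence = si)
      }
    }
  }
  if (length(comentions) == 0) return(structure(0L, comentions = list()))
  key <- vapply(comentions, function(cm) idx_key(cm$gene, cm$term), character(1))
  added <- 0L
  for (pk in unique(key)) {
    cms <- comentions[key == pk]
    pubs <- unique(vapply(cms, function(cm) cm$publication, numeric(1)))
    pmids <- sort(unique(vapply(cms, function(cm) cm$pmid, character(1))))
    before <- kg_relation_count(g)
    add_relation(g, cms[[1]]$gene, cms[[1]]$term, type,
                 attributes = list(CoCitations = length(pubs),
                                   PMIDs = paste(pmids[!is.na(pmids)],
                                                 collapse = ";")),
                 source = "TM", evidence = "TM")
    if (kg_relation_count(g) > before) added <- added + 1L
  }
  structure(added, comentions = comentions)
}
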