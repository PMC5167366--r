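#' The knowledge-network meta-model
#'
#' Every element of a knowledge network is typed against a meta-model: a
#' controlled vocabulary of *concept classes* (Gene, Protein, QTL, ...),
#' *relation types* (encodes, equal, ortholog, ...), *data sources*,
#' *attribute names* (each with a value kind) and *evidence types*.
#' Concept-class and relation-type vocabularies are hierarchical (each entry
#' may name a parent) and must be acyclic.
#'
#' `metamodel()` builds a meta-model from its five component tables;
#' `metamodel_default()` returns the vocabulary shipped with the package,
#' which covers the standard crop-GSKN sources (gene models, ontologies,
#' GO annotations, SNP/QTL genetics, homology, domains, pathways,
#' phenotypes, literature).
#'
#' @param concept_classes data.frame with columns `id`, `label`, `parent`
#'   (`NA` for roots).
#' @param relation_types data.frame with columns `id`, `label`, `parent`,
#'   `symmetric` (logical; symmetric types store one relation per unordered
#'   endpoint pair).
#' @param data_sources data.frame with columns `id`, `label`.
#' @param attribute_names data.frame with columns `id`, `kind`; kind is one
#'   of `"text"`, `"integer"`, `"decimal"`, `"location"`, `"sequence"`.
#' @param evidence_types data.frame with columns `id`, `label`.
#' @return An object of class `gsknet_metamodel`.
#' @examples
#' m <- metamodel_default()
#' "Gene" %in% m$concept_classes$id
#' @export
metamodel <- function(concept_classes, relation_types, data_sources,
                      attribute_names, evidence_types) {
  m <- structure(list(
    concept_classes = normalise_vocab(concept_classes, c("id", "label", "parent")),
    relation_types  = normalise_vocab(relation_types,  c("id", "label", "parent", "symmetric")),
    data_sources    = normalise_vocab(data_sources,    c("id", "label")),
    attribute_names = normalise_vocab(attribute_names, c("id", "kind")),
    evidence_types  = normalise_vocab(evidence_types,  c("id", "label"))
  ), class = "gsknet_metamodel")
  validate_metamodel(m)
  m
}

normalise_vocab <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) meta_error("vocabulary table lacks an 'id' column")
  if ("label" %in% cols && !"label" %in% names(df)) df$label <- df$id
  if ("parent" %in% cols && !"parent" %in% names(df)) df$parent <- NA_character_
  if ("symmetric" %in% cols && !"symmetric" %in% names(df)) df$symmetric <- FALSE
  if ("kind" %in% cols && !"kind" %in% names(df)) meta_error("attribute table lacks a 'kind' column")
  df <- df[, cols, drop = FALSE]
  df$id <- as.character(df$id)
  if ("parent" %in% cols) df$parent <- as.character(df$parent)
  if ("symmetric" %in% cols) df$symmetric <- as.logical(df$symmetric) %in% TRUE
  rownames(df) <- NULL
  df
}

VALUE_KINDS <- c("text", "integer", "decimal", "location", "sequence")

validate_metamodel <- function(m) {
  problems <- character(0)
  for (cat in names(m)) {
    ids <- m[[cat]]$id
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      problems <- c(problems, sprintf("%s: duplicate id(s) %s", cat,
                                      paste(dup, collapse = ", ")))
  }
  for (cat in c("concept_classes", "relation_types")) {
    tab <- m[[cat]]
    bad <- !is.na(tab$parent) & !(tab$parent %in% tab$id)
    if (any(bad))
      problems <- c(problems, sprintf("%s: unresolved parent(s) %s", cat,
                                      paste(tab$parent[bad], collapse = ", ")))
    cyc <- hierarchy_cycle(tab$id, tab$parent)
    if (length(cyc))
      problems <- c(problems, sprintf("%s: cyclic hierarchy through %s", cat,
                                      paste(cyc, collapse = " -> ")))
  }
  bad_kind <- !(m$attribute_names$kind %in% VALUE_KINDS)
  if (any(bad_kind))
    problems <- c(problems, sprintf("attribute_names: unknown kind(s) %s",
                                    paste(unique(m$attribute_names$kind[bad_kind]), collapse = ", ")))
  if (length(problems))
    meta_error("invalid meta-model:\n%s", paste("-", problems, collapse = "\n"))
  invisible(m)
}

# returns the ids on a cycle (empty if acyclic); iterative parent-chasing
hierarchy_cycle <- function(ids, parents) {
  parent_of <- setNames(parents, ids)
  state <- setNames(rep(0L, length(ids)), ids)   # 0 unseen, 1 on stack, 2 done
  for (start in ids) {
    if (state[[start]] != 0L) next
    chain <- character(0)
    node <- start
    while (!is.na(node) && node %in% ids && state[[node]] == 0L) {
      state[[node]] <- 1L
      chain <- c(chain, node)
      node <- parent_of[[node]]
    }
    if (!is.na(node) && node %in% ids && state[[node]] == 1L)
      return(c(chain[which(chain == node):length(chain)], node))
    state[chain] <- 2L
  }
  character(0)
}

.default_meta_cache <- new.env(parent = emptyenv())

#' @rdname metamodel
#' @export
metamodel_default <- function() {
  if (is.null(.default_meta_cache$meta)) {
    path <- system.file("extdata", "metamodel.yaml", package = "gsknet",
                        mustWork = TRUE)
    .default_meta_cache$meta <- read_metamodel(path)
  }
  .default_meta_cache$meta
}

#' Read / write a meta-model as YAML
#'
#' The meta-model serialises as a YAML document with five sequences
#' (`concept_classes`, `relation_types`, `data_sources`, `attribute_names`,
#' `evidence_types`), each entry a mapping of the table's columns.
#'
#' @param path file path.
#' @param m a `gsknet_metamodel`.
#' @return `read_metamodel()` returns a `gsknet_metamodel`;
#'   `write_metamodel()` returns `path` invisibly.
#' @export
read_metamodel <- function(path) {
  doc <- yaml::read_yaml(path)
  bind <- function(entries, cols) {
    rows <- lapply(entries, function(e) {
      e <- e[!vapply(e, is.null, logical(1))]
      miss <- setdiff(cols, names(e))
      for (mcol in miss) e[[mcol]] <- if (mcol == "symmetric") FALSE else NA
      as.data.frame(e[cols], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  metamodel(
    concept_classes = bind(doc$concept_classes, c("id", "label", "parent")),
    relation_types  = bind(doc$relation_types,  c("id", "label", "parent", "symmetric")),
    data_sources    = bind(doc$data_sources,    c("id", "label")),
    attribute_names = bind(doc$attribute_names, c("id", "kind")),
    evidence_types  = bind(doc$evidence_types,  c("id", "label"))
  )
}

#' @rdname read_metamodel
#' @export
write_metamodel <- function(m, path) {
  stopifnot(inherits(m, "gsknet_metamodel"))
  row_list <- function(df) lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    r <- r[!vapply(r, function(v) is.na(v) || identical(v, FALSE), logical(1))]
    lapply(r, function(v) if (is.logical(v)) v else as.character(v))
  })
  doc <- lapply(m, row_list)
  yaml::write_yaml(doc, path)
  invisible(path)
}

meta_has <- function(m, category, id) id %in% m[[category]]$id

attr_kind <- function(m, attr_id) {
  k <- m$attribute_names$kind[match(attr_id, m$attribute_names$id)]
  if (is.na(k)) meta_error("unknown attribute name '%s'", attr_id)
  k
}

is_symmetric_type <- function(m, type_id) {
  s <- m$relation_types$symmetric[match(type_id, m$relation_types$id)]
  isTRUE(s)
}

#' @export
print.gsknet_metamodel <- function(x, ...) {
  cat(sprintf(
    "<gsknet meta-model: %d concept classes, %d relation types, %d data sources, %d attribute names, %d evidence types>\n",
    nrow(x$concept_classes), nrow(x$relation_types), nrow(x$data_sources),
    nrow(x$attribute_names), nrow(x$evidence_types)))
  invisible(x)
}
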