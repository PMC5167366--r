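#' XML exchange format
#'
#' Lossless, deterministic serialisation of a knowledge graph as a
#' versioned XML document (an OXL-style exchange file). The document holds
#' the full meta-model followed by all concepts (ordered by id) and all
#' relations (ordered by id); every attribute value is written with an
#' explicit kind tag so that `read_oxl(write_oxl(g))` reproduces the graph
#' exactly, ids included. Output is byte-deterministic for equal inputs.
#'
#' Schema (root `<gsknet version="1.0">`): a `<metamodel>` section with
#' `<conceptClass/>`, `<relationType/>`, `<dataSource/>`, `<attributeName/>`
#' and `<evidenceType/>` elements; a `<concepts>` section of `<concept>`
#' elements each holding `<accession/>`, `<name>`, `<attribute>`,
#' `<source/>` and `<evidence/>` children; and a matching `<relations>`
#' section. Location-kind attribute values serialise as a `<loc/>` element
#' with chromosome/begin/end/unit/taxid fields.
#'
#' @param g a `kg`.
#' @param path destination (write) / source (read) file path; `.gz` sources
#'   are read transparently.
#' @return `write_oxl()` returns `path` invisibly; `read_oxl()` a `kg`.
#' @export
write_oxl <- function(g, path) {
  stopifnot(inherits(g, "kg"))
  out <- vector("list", 0)
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<gsknet version="1.0">')
  push(' <metamodel>')
  m <- g$meta
  for (i in seq_len(nrow(m$concept_classes))) {
    r <- m$concept_classes[i, ]
    push('  <conceptClass id="', xesc(r$id), '" label="', xesc(r$label), '"',
         if (!is.na(r$parent)) paste0(' parent="', xesc(r$parent), '"'), '/>')
  }
  for (i in seq_len(nrow(m$relation_types))) {
    r <- m$relation_types[i, ]
    push('  <relationType id="', xesc(r$id), '" label="', xesc(r$label), '"',
         if (!is.na(r$parent)) paste0(' parent="', xesc(r$parent), '"'),
         ' symmetric="', tolower(as.character(r$symmetric)), '"/>')
  }
  for (i in seq_len(nrow(m$data_sources)))
    push('  <dataSource id="', xesc(m$data_sources$id[i]), '" label="',
         xesc(m$data_sources$label[i]), '"/>')
  for (i in seq_len(nrow(m$attribute_names)))
    push('  <attributeName id="', xesc(m$attribute_names$id[i]), '" kind="',
         m$attribute_names$kind[i], '"/>')
  for (i in seq_len(nrow(m$evidence_types)))
    push('  <evidenceType id="', xesc(m$evidence_types$id[i]), '" label="',
         xesc(m$evidence_types$label[i]), '"/>')
  push(' </metamodel>')

  push(' <concepts>')
  for (cid in kg_concept_ids(g)) {
    con <- g$concepts[[as.character(cid)]]
    push('  <concept id="', con$id, '" class="', xesc(con$class), '">')
    for (a in con$accessions)
      push('   <accession ns="', xesc(a$namespace), '" value="', xesc(a$value),
           '" ambiguous="', tolower(as.character(a$ambiguous)), '"/>')
    if (nrow(con$names))
      for (i in seq_len(nrow(con$names)))
        push('   <name preferred="', tolower(as.character(con$names$preferred[i])),
             '">', xesc(con$names$name[i]), '</name>')
    out <- c(out, as.list(attr_xml(g, con$attributes)))
    for (s in con$provenance) push('   <source id="', xesc(s), '"/>')
    for (e in con$evidence) push('   <evidence id="', xesc(e), '"/>')
    push('  </concept>')
  }
  push(' </concepts>')

  push(' <relations>')
  for (rid in kg_relation_ids(g)) {
    rel <- g$relations[[as.character(rid)]]
    push('  <relation id="', rel$id, '" from="', rel$from, '" to="', rel$to,
         '" type="', xesc(rel$type), '">')
    out <- c(out, as.list(attr_xml(g, rel$attributes)))
    for (s in rel$provenance) push('   <source id="', xesc(s), '"/>')
    for (e in rel$evidence) push('   <evidence id="', xesc(e), '"/>')
    push('  </relation>')
  }
  push(' </relations>')
  push('</gsknet>')
  write_lines_lf(unlist(out), path)
  invisible(path)
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

attr_xml <- function(g, attributes) {
  if (length(attributes) == 0) return(character(0))
  keys <- sort(names(attributes))
  vapply(keys, function(k) {
    v <- attributes[[k]]
    kind <- attr_kind(g$meta, k)
    if (kind == "location") {
      if (!is_location(v))
        stop_gsknet("attribute '%s' declared location-kind but value is not a location", k,
                    class = "gsknet_export_error")
      paste0('   <attribute name="', xesc(k), '" kind="location">',
             '<loc chrom="', xesc(v$chromosome), '" begin="', fmt_num(v$begin),
             '" end="', fmt_num(v$end), '" unit="', v$unit, '" taxid="',
             xesc(v$taxid), '"/></attribute>')
    } else if (kind %in% c("integer", "decimal")) {
      if (!is.numeric(v))
        stop_gsknet("attribute '%s' of kind %s has non-numeric value", k, kind,
                    class = "gsknet_export_error")
      paste0('   <attribute name="', xesc(k), '" kind="', kind, '">',
             fmt_num(v), '</attribute>')
    } else if (kind %in% c("text", "sequence")) {
      paste0('   <attribute name="', xesc(k), '" kind="', kind, '">',
             xesc(as.character(v)), '</attribute>')
    } else {
      stop_gsknet("cannot serialise attribute '%s' of kind '%s'", k, kind,
                  class = "gsknet_export_error")
    }
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname write_oxl
#' @export
read_oxl <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) parse_error("not a well-formed exchange document: %s",
                                                  conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "gsknet")
    parse_error("unexpected root element <%s>; expected <gsknet>", root)

  mm <- xml2::xml_find_first(doc, "./metamodel")
  if (inherits(mm, "xml_missing"))
    parse_error("document lacks a <metamodel> section")
  grab <- function(tag, cols) {
    ns <- xml2::xml_find_all(mm, paste0("./", tag))
    if (length(ns) == 0)
      return(as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                           stringsAsFactors = FALSE))
    df <- as.data.frame(lapply(cols, function(cl) xml2::xml_attr(ns, cl)),
                        col.names = cols, stringsAsFactors = FALSE)
    if ("symmetric" %in% cols) df$symmetric <- df$symmetric == "true"
    df
  }
  meta <- metamodel(
    concept_classes = grab("conceptClass", c("id", "label", "parent")),
    relation_types  = grab("relationType", c("id", "label", "parent", "symmetric")),
    data_sources    = grab("dataSource", c("id", "label")),
    attribute_names = grab("attributeName", c("id", "kind")),
    evidence_types  = grab("evidenceType", c("id", "label"))
  )
  g <- kg_new(meta)

  read_attrs <- function(node) {
    ans <- list()
    for (an in xml2::xml_find_all(node, "./attribute")) {
      key <- xml2::xml_attr(an, "name")
      kind <- xml2::xml_attr(an, "kind")
      if (!meta_has(meta, "attribute_names", key))
        meta_error("document uses undeclared attribute name '%s'", key)
      ans[[key]] <- switch(kind,
        location = {
          ln <- xml2::xml_find_first(an, "./loc")
          genomic_location(xml2::xml_attr(ln, "chrom"),
                           as.numeric(xml2::xml_attr(ln, "begin")),
                           as.numeric(xml2::xml_attr(ln, "end")),
                           xml2::xml_attr(ln, "unit"),
                           xml2::xml_attr(ln, "taxid"))
        },
        integer = {
          v <- as.numeric(xml2::xml_text(an))
          if (v == floor(v) && abs(v) < 2^31) as.integer(v) else v
        },
        decimal = as.numeric(xml2::xml_text(an)),
        text = xml2::xml_text(an),
        sequence = xml2::xml_text(an),
        parse_error("unknown attribute kind '%s'", kind))
    }
    ans
  }

  for (cn in xml2::xml_find_all(doc, "./concepts/concept")) {
    cid <- as.integer(xml2::xml_attr(cn, "id"))
    class <- xml2::xml_attr(cn, "class")
    if (!meta_has(meta, "concept_classes", class))
      meta_error("document references undeclared concept class '%s'", class)
    accs <- lapply(xml2::xml_find_all(cn, "./accession"), function(a)
      acc(xml2::xml_attr(a, "ns"), xml2::xml_attr(a, "value"),
          xml2::xml_attr(a, "ambiguous") == "true"))
    name_nodes <- xml2::xml_find_all(cn, "./name")
    names_df <- data.frame(name = xml2::xml_text(name_nodes),
                           preferred = xml2::xml_attr(name_nodes, "preferred") == "true",
                           stringsAsFactors = FALSE)
    con <- list(id = cid, class = class, accessions = accs, names = names_df,
                attributes = read_attrs(cn),
                provenance = xml2::xml_attr(xml2::xml_find_all(cn, "./source"), "id"),
                evidence = xml2::xml_attr(xml2::xml_find_all(cn, "./evidence"), "id"))
    g$concepts[[as.character(cid)]] <- con
    index_concept(g, con)
    g$next_cid <- max(g$next_cid, cid + 1L)
  }

  for (rn in xml2::xml_find_all(doc, "./relations/relation")) {
    type <- xml2::xml_attr(rn, "type")
    if (!meta_has(meta, "relation_types", type))
      meta_error("document references undeclared relation type '%s'", type)
    rid <- as.integer(xml2::xml_attr(rn, "id"))
    from <- as.integer(xml2::xml_attr(rn, "from"))
    to <- as.integer(xml2::xml_attr(rn, "to"))
    if (is.null(g$concepts[[as.character(from)]]) ||
        is.null(g$concepts[[as.character(to)]]))
      parse_error("relation %d references a missing concept", rid)
    rel <- list(id = rid, from = from, to = to, type = type,
                attributes = read_attrs(rn),
                provenance = xml2::xml_attr(xml2::xml_find_all(rn, "./source"), "id"),
                evidence = xml2::xml_attr(xml2::xml_find_all(rn, "./evidence"), "id"))
    g$relations[[as.character(rid)]] <- rel
    g$rel_index[[idx_key(from, to, type)]] <- rid
    idx_add(g$adj, as.character(from), rid)
    if (to != from) idx_add(g$adj, as.character(to), rid)
    g$next_rid <- max(g$next_rid, rid + 1L)
  }
  g
}

#' Node-link JSON export
#'
#' Writes the graph in generic node-link form for graph viewers
#' (Cytoscape-style): a `nodes` array of `{id, class, name, accessions}`
#' records and an `edges` array of `{id, from, to, type}` records.
#'
#' @param g a `kg`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_json_graph <- function(g, path) {
  stopifnot(inherits(g, "kg"))
  nodes <- lapply(kg_concept_ids(g), function(cid) {
    con <- g$concepts[[as.character(cid)]]
    list(id = con$id, class = con$class,
         name = if (nrow(con$names)) kg_preferred_name(g, cid) else NULL,
         accessions = vapply(con$accessions,
                             function(a) paste0(a$namespace, ":", a$value),
                             character(1)))
  })
  edges <- lapply(kg_relation_ids(g), function(rid) {
    rel <- g$relations[[as.character(rid)]]
    list(id = rel$id, from = rel$from, to = rel$to, type = rel$type)
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, pretty = FALSE, digits = NA)
  invisible(path)
}
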