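#' Traversal filters
#'
#' Restricts graph traversals to selected concept classes and relation
#' types, a maximum depth and an edge direction. Evidence chains typically
#' cross relation directions (a QTL *controls* a trait while a gene is
#' *colocated* with the QTL), so the default direction is `"both"`.
#'
#' @param classes allowed concept classes (`NULL` = all). Seeds are always
#'   included regardless.
#' @param types allowed relation types (`NULL` = all).
#' @param max_depth maximum number of relations from a seed (>= 1).
#' @param direction `"both"`, `"forward"` (follow from -> to only) or
#'   `"reverse"`.
#' @return list of class `gsknet_filter`.
#' @export
traversal_filter <- function(classes = NULL, types = NULL, max_depth = 1L,
                             direction = c("both", "forward", "reverse")) {
  if (max_depth < 1) graph_error("max_depth must be >= 1")
  structure(list(classes = classes, types = types,
                 max_depth = as.integer(max_depth),
                 direction = match.arg(direction)),
            class = "gsknet_filter")
}

# neighbours of `cid` reachable over one allowed relation; returns
# list(ids, rids)
step_neighbours <- function(g, cid, filter) {
  rids <- idx_get(g$adj, as.character(cid))
  ids <- integer(0); keep_r <- integer(0)
  for (rid in rids) {
    rel <- g$relations[[as.character(rid)]]
    if (!is.null(filter$types) && !(rel$type %in% filter$types)) next
    sym <- is_symmetric_type(g$meta, rel$type)
    other <- if (rel$from == cid) rel$to else rel$from
    if (!sym && filter$direction == "forward" && rel$from != cid) next
    if (!sym && filter$direction == "reverse" && rel$to != cid) next
    if (!is.null(filter$classes) &&
        !(g$concepts[[as.character(other)]]$class %in% filter$classes)) next
    ids <- c(ids, other); keep_r <- c(keep_r, rid)
  }
  list(ids = unique(ids), rids = keep_r)
}

#' Neighbourhood search
#'
#' Extracts the subgraph of all concepts reachable from any seed within
#' `filter$max_depth` relations, traversing only allowed relation types and
#' entering only allowed concept classes. Seeds are always included. The
#' result keeps every allowed relation between two retained concepts.
#'
#' @param g a `kg`.
#' @param seeds concept ids.
#' @param filter a [traversal_filter()].
#' @return a new `kg` (ids preserved).
#' @export
kg_neighborhood <- function(g, seeds, filter = traversal_filter(max_depth = 1L)) {
  stopifnot(inherits(g, "kg"))
  for (s in seeds)
    if (is.null(g$concepts[[as.character(s)]]))
      graph_error("unknown seed concept %s", s)
  visited <- new.env(parent = emptyenv())
  frontier <- unique(as.integer(seeds))
  for (s in frontier) visited[[as.character(s)]] <- TRUE
  depth <- 0L
  while (length(frontier) && depth < filter$max_depth) {
    nxt <- integer(0)
    for (cid in frontier) {
      st <- step_neighbours(g, cid, filter)
      for (o in st$ids) {
        key <- as.character(o)
        if (is.null(visited[[key]])) { visited[[key]] <- TRUE; nxt <- c(nxt, o) }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  members <- as.integer(ls(visited))
  rids <- Filter(function(rid) {
    rel <- g$relations[[as.character(rid)]]
    (is.null(filter$types) || rel$type %in% filter$types) &&
      !is.null(visited[[as.character(rel$from)]]) &&
      !is.null(visited[[as.character(rel$to)]])
  }, kg_relation_ids(g))
  kg_subgraph(g, members, rids)
}

#' Shortest evidence path
#'
#' Finds a minimum-length path between two concepts under a traversal
#' filter (default: undirected view, all classes/types, unlimited depth).
#' Among equal-length paths the lexicographically smallest concept-id
#' sequence is returned, so results are reproducible. Returns `NULL` when
#' the concepts are not connected within `max_depth`.
#'
#' @param g a `kg`.
#' @param a,b concept ids.
#' @param filter a [traversal_filter()]; `max_depth` bounds the search.
#' @return list of class `gsknet_path` with `concepts` (id sequence),
#'   `relations` (id sequence, one shorter) and `length` (relation count),
#'   or `NULL`.
#' @export
kg_shortest_path <- function(g, a, b,
                             filter = traversal_filter(max_depth = .Machine$integer.max)) {
  stopifnot(inherits(g, "kg"))
  a <- as.integer(a); b <- as.integer(b)
  for (s in c(a, b))
    if (is.null(g$concepts[[as.character(s)]]))
      graph_error("unknown concept %s", s)
  if (a == b)
    return(structure(list(concepts = a, relations = integer(0), length = 0L),
                     class = "gsknet_path"))

  dist_from <- function(start, flt) {
    d <- new.env(parent = emptyenv())
    d[[as.character(start)]] <- 0L
    frontier <- start
    depth <- 0L
    while (length(frontier) && depth < flt$max_depth) {
      depth <- depth + 1L
      nxt <- integer(0)
      for (cid in frontier) {
        for (o in step_neighbours(g, cid, flt)$ids) {
          key <- as.character(o)
          if (is.null(d[[key]])) { d[[key]] <- depth; nxt <- c(nxt, o) }
        }
      }
      frontier <- nxt
    }
    d
  }
  # distances computed from b with the direction reversed, so the forward
  # walk from a respects the filter's direction
  back_filter <- filter
  back_filter$direction <- switch(filter$direction, both = "both",
                                  forward = "reverse", reverse = "forward")
  db <- dist_from(b, back_filter)
  total <- db[[as.character(a)]]
  if (is.null(total)) return(NULL)

  # walk forward from a, always taking the smallest-id neighbour that still
  # lies on some shortest path (distance to b decreases by one each step)
  path <- a
  rels <- integer(0)
  cur <- a
  remaining <- total
  while (remaining > 0L) {
    st <- step_neighbours(g, cur, filter)
    cand <- st$ids[vapply(st$ids, function(o) {
      dv <- db[[as.character(o)]]
      !is.null(dv) && dv == remaining - 1L
    }, logical(1))]
    nxt <- min(cand)
    # the relation used (smallest rid among parallels between cur and nxt)
    rsel <- Filter(function(rid) {
      rel <- g$relations[[as.character(rid)]]
      (rel$from == cur && rel$to == nxt) || (rel$from == nxt && rel$to == cur)
    }, st$rids)
    rels <- c(rels, min(unlist(rsel)))
    path <- c(path, nxt)
    cur <- nxt
    remaining <- remaining - 1L
  }
  structure(list(concepts = path, relations = rels, length = total),
            class = "gsknet_path")
}

#' @export
print.gsknet_path <- function(x, ...) {
  cat(sprintf("<evidence path: length %d; concepts %s>\n", x$length,
              paste(x$concepts, collapse = " - ")))
  invisible(x)
}

#' Default gene-evidence meta-paths
#'
#' Class/type templates describing the evidence chains collected around a
#' gene: its co-located QTLs and their traits; the protein it encodes, that
#' protein's domains and their GO cross-references; orthologs and their
#' observed phenotypes and publications; and text-mined trait-ontology
#' links. Each template is a character vector alternating concept classes
#' and relation types; a class element may offer alternatives separated by
#' `|`. Templates are matched on the undirected view.
#'
#' @return list of character vectors.
#' @export
default_meta_paths <- function() {
  list(
    c("Gene", "colocated", "QTL", "control", "Trait"),
    c("Gene", "has_variance", "SNP"),
    c("Gene", "encodes", "Protein", "has_domain", "ProtDomain",
      "cross_reference", "BioProc|MolFunc|CelComp"),
    c("Gene", "encodes", "Protein", "ortholog", "Protein",
      "has_observed_phenotype", "Phenotype"),
    c("Gene", "encodes", "Protein", "ortholog", "Protein",
      "published_in", "Publication"),
    c("Gene", "encodes", "Protein", "has_similar_sequence", "Protein"),
    c("Gene", "cooccurs_with", "TO")
  )
}

#' Gene-evidence network extraction
#'
#' Builds the union of all instances of the given meta-path templates
#' anchored at a gene: the candidate-gene discovery output linking a gene
#' to its QTLs, traits, domains, GO terms, orthologs, phenotypes and
#' publications. The result is a connected subgraph containing the anchor.
#'
#' @param g a `kg`.
#' @param gene concept id of the anchor (class Gene).
#' @param meta_paths list of templates, see [default_meta_paths()].
#' @return a new `kg` (ids preserved).
#' @export
evidence_network <- function(g, gene, meta_paths = default_meta_paths()) {
  stopifnot(inherits(g, "kg"))
  con <- kg_concept(g, gene)
  if (con$class != "Gene")
    graph_error("evidence_network anchor must be a Gene (got %s)", con$class)
  keep_c <- new.env(parent = emptyenv())
  keep_r <- new.env(parent = emptyenv())
  keep_c[[as.character(gene)]] <- TRUE

  class_ok <- function(pattern, class) class %in% strsplit(pattern, "|", fixed = TRUE)[[1]]

  # depth-first enumeration of template instances; records every prefix so
  # partial instances (e.g. a gene whose protein has no domain) still
  # contribute their concepts
  walk <- function(cid, tpl, pos, trail_c, trail_r) {
    if (pos > length(tpl)) {
      for (x in trail_c) keep_c[[as.character(x)]] <- TRUE
      for (x in trail_r) keep_r[[as.character(x)]] <- TRUE
      return(invisible(NULL))
    }
    type <- tpl[pos]
    next_class <- tpl[pos + 1L]
    for (rid in idx_get(g$adj, as.character(cid))) {
      rel <- g$relations[[as.character(rid)]]
      if (rel$type != type) next
      other <- if (rel$from == cid) rel$to else rel$from
      if (other == cid) next
      if (!class_ok(next_class, g$concepts[[as.character(other)]]$class)) next
      if (other %in% trail_c) next
      # record the completed prefix up to `other`
      for (x in c(trail_c, other)) keep_c[[as.character(x)]] <- TRUE
      for (x in c(trail_r, rid)) keep_r[[as.character(x)]] <- TRUE
      walk(other, tpl, pos + 2L, c(trail_c, other), c(trail_r, rid))
    }
  }

  for (tpl in meta_paths) {
    if (!class_ok(tpl[1], con$class)) next
    walk(gene, tpl, 2L, gene, integer(0))
  }
  kg_subgraph(g, as.integer(ls(keep_c)), as.integer(ls(keep_r)))
}
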