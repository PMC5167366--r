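#' Create an empty knowledge graph
#'
#' A knowledge graph is a typed, labelled, directed multigraph. Nodes
#' ("concepts") and edges ("relations") are typed against a [metamodel()]
#' and carry accessions, names, attributes, provenance (data sources) and
#' evidence types. The object has reference semantics: all `kg_*`,
#' `upsert_*`, `*_map` and `collapse_*` functions mutate the graph in place
#' and return counts or ids. Use [kg_clone()] for an independent copy.
#'
#' Parallel edges between the same pair of concepts are allowed provided
#' their relation types differ; a second relation with an identical
#' (from, to, type) triple is merged into the first.
#'
#' @param meta a [metamodel()]; defaults to the packaged vocabulary.
#' @return An object of class `kg` (an environment).
#' @examples
#' g <- kg_new()
#' kg_concept_count(g)
#' @export
kg_new <- function(meta = metamodel_default()) {
  if (!inherits(meta, "gsknet_metamodel"))
    meta_error("meta must be a gsknet_metamodel")
  validate_metamodel(meta)
  g <- new.env(parent = emptyenv())
  g$meta <- meta
  g$concepts <- new.env(hash = TRUE, parent = emptyenv())
  g$relations <- new.env(hash = TRUE, parent = emptyenv())
  g$acc_index <- new.env(hash = TRUE, parent = emptyenv())   # ns\x1fvalue -> cids
  g$name_index <- new.env(hash = TRUE, parent = emptyenv())  # norm name -> cids
  g$rel_index <- new.env(hash = TRUE, parent = emptyenv())   # from\x1fto\x1ftype -> rid
  g$adj <- new.env(hash = TRUE, parent = emptyenv())         # cid -> rids touching it
  g$audit <- list()                                          # merge overwrite trail
  g$next_cid <- 1L
  g$next_rid <- 1L
  class(g) <- "kg"
  g
}

#' @rdname kg_new
#' @param g a `kg`.
#' @export
kg_clone <- function(g) {
  h <- kg_new(g$meta)
  for (f in c("concepts", "relations", "acc_index", "name_index", "rel_index", "adj"))
    for (k in ls(g[[f]])) h[[f]][[k]] <- g[[f]][[k]]
  h$audit <- g$audit
  h$next_cid <- g$next_cid
  h$next_rid <- g$next_rid
  h
}

#' Accession constructor
#'
#' An accession is a (namespace, value) identifier pair; the namespace is a
#' data-source id. Accessions flagged `ambiguous` are stored and exported
#' but never drive concept merging or accession-based mapping.
#'
#' @param namespace data-source id (e.g. `"ENSEMBL"`).
#' @param value identifier string, non-empty.
#' @param ambiguous logical flag.
#' @return list of class `gsknet_accession`.
#' @export
acc <- function(namespace, value, ambiguous = FALSE) {
  if (!nzchar(value)) graph_error("accession value must be non-empty")
  structure(list(namespace = as.character(namespace),
                 value = as.character(value),
                 ambiguous = isTRUE(ambiguous)),
            class = "gsknet_accession")
}

normalise_accessions <- function(accessions) {
  if (is.null(accessions) || length(accessions) == 0) return(list())
  if (inherits(accessions, "gsknet_accession")) return(list(accessions))
  lapply(accessions, function(a) {
    if (inherits(a, "gsknet_accession")) a
    else acc(a$namespace %||% a[[1]], a$value %||% a[[2]],
             isTRUE(a$ambiguous %||% FALSE))
  })
}

# register open-vocabulary entries (data sources, evidence types) on first use
ensure_source <- function(g, id) {
  if (!meta_has(g$meta, "data_sources", id))
    g$meta$data_sources <- rbind(g$meta$data_sources,
                                 data.frame(id = id, label = id,
                                            stringsAsFactors = FALSE))
  invisible(id)
}

ensure_evidence <- function(g, id) {
  new <- setdiff(id, g$meta$evidence_types$id)
  if (length(new))
    g$meta$evidence_types <- rbind(g$meta$evidence_types,
                                   data.frame(id = new, label = new,
                                              stringsAsFactors = FALSE))
  invisible(id)
}

check_attributes <- function(g, attributes) {
  if (length(attributes) == 0) return(invisible(NULL))
  if (is.null(names(attributes)) || any(!nzchar(names(attributes))))
    meta_error("attributes must be a named list")
  unknown <- setdiff(names(attributes), g$meta$attribute_names$id)
  if (length(unknown))
    meta_error("attribute name(s) not in meta-model: %s",
               paste(unknown, collapse = ", "))
  invisible(NULL)
}

#' Create or merge a concept
#'
#' If `merge = TRUE` (the default) and any non-ambiguous accession of the
#' new concept is already held by an existing concept *of the same class*,
#' that concept is enriched instead of a new one being created: accessions,
#' names, provenance and evidence are unioned and attributes merged
#' (last-writer-wins per key; overwritten values are retained in the
#' graph's audit trail, see [kg_audit()]). Parsers rely on this to merge
#' concepts sharing accessions within a parsed dataset.
#'
#' @param g a [kg_new()] graph (mutated in place).
#' @param class concept-class id from the meta-model.
#' @param accessions list of [acc()] accessions.
#' @param preferred_name optional preferred name.
#' @param synonyms character vector of additional names.
#' @param attributes named list; names must be meta-model attribute names.
#' @param source data-source id recorded as provenance.
#' @param evidence character vector of evidence-type ids.
#' @param merge logical; merge on shared accessions (see above).
#' @return The concept id (integer), invisibly usable for [add_relation()].
#' @export
upsert_concept <- function(g, class, accessions = list(), preferred_name = NULL,
                           synonyms = character(0), attributes = list(),
                           source = "UC", evidence = "IMPD", merge = TRUE) {
  stopifnot(inherits(g, "kg"))
  if (!meta_has(g$meta, "concept_classes", class))
    meta_error("unknown concept class '%s'", class)
  check_attributes(g, attributes)
  accessions <- normalise_accessions(accessions)
  ensure_source(g, source)
  ensure_evidence(g, evidence)

  target <- NA_integer_
  if (merge) {
    hits <- integer(0)
    for (a in accessions) {
      if (a$ambiguous) next
      h <- idx_get(g$acc_index, idx_key(a$namespace, a$value))
      h <- h[vapply(h, function(id)
        g$concepts[[as.character(id)]]$class == class, logical(1))]
      hits <- c(hits, h)
    }
    hits <- sort(unique(hits))
    # a record bridging several existing concepts merges them all, so no
    # two same-class concepts ever share a non-ambiguous accession
    if (length(hits) > 1) target <- merge_concepts(g, hits)
    else if (length(hits) == 1) target <- hits
  }

  names_df <- concept_names_df(preferred_name, synonyms)
  if (is.na(target)) {
    cid <- g$next_cid
    g$next_cid <- g$next_cid + 1L
    con <- list(id = cid, class = class, accessions = accessions,
                names = names_df, attributes = attributes,
                provenance = source, evidence = unique(evidence))
    g$concepts[[as.character(cid)]] <- con
    index_concept(g, con)
    return(cid)
  }

  enrich_concept(g, target, accessions, names_df, attributes, source, evidence)
  target
}

concept_names_df <- function(preferred_name, synonyms) {
  nm <- c(if (!is.null(preferred_name) && nzchar(preferred_name)) preferred_name,
          synonyms[nzchar(synonyms)])
  if (length(nm) == 0)
    return(data.frame(name = character(0), preferred = logical(0),
                      stringsAsFactors = FALSE))
  pref <- !is.null(preferred_name) && nzchar(preferred_name)
  df <- data.frame(name = nm,
                   preferred = c(if (pref) TRUE, rep(FALSE, length(nm) - pref)),
                   stringsAsFactors = FALSE)
  df[!duplicated(df$name), , drop = FALSE]
}

index_concept <- function(g, con) {
  for (a in con$accessions)
    idx_add(g$acc_index, idx_key(a$namespace, a$value), con$id)
  for (nm in con$names$name)
    idx_add(g$name_index, norm_name(nm), con$id)
}

unindex_concept <- function(g, con) {
  for (a in con$accessions)
    idx_remove(g$acc_index, idx_key(a$namespace, a$value), con$id)
  for (nm in con$names$name)
    idx_remove(g$name_index, norm_name(nm), con$id)
}

# union accessions/names/provenance/evidence into concept `cid`;
# attributes merge last-writer-wins with audit of overwritten values
enrich_concept <- function(g, cid, accessions, names_df, attributes,
                           source, evidence) {
  key <- as.character(cid)
  con <- g$concepts[[key]]
  have <- vapply(con$accessions, function(a) idx_key(a$namespace, a$value), character(1))
  for (a in accessions) {
    k <- idx_key(a$namespace, a$value)
    if (!(k %in% have)) {
      con$accessions <- c(con$accessions, list(a))
      idx_add(g$acc_index, k, cid)
      have <- c(have, k)
    }
  }
  if (nrow(names_df)) {
    if (any(con$names$preferred)) names_df$preferred <- FALSE  # keep existing preferred
    new <- names_df[!(names_df$name %in% con$names$name), , drop = FALSE]
    if (nrow(new)) {
      if (!any(con$names$preferred) && any(names_df$preferred)) {
        # no preferred yet: promote the incoming preferred if it survived dedup
        pn <- names_df$name[names_df$preferred][1]
        new$preferred <- new$name == pn
      }
      con$names <- rbind(con$names, new)
      for (nm in new$name) idx_add(g$name_index, norm_name(nm), cid)
    }
  }
  for (k in names(attributes)) {
    old <- con$attributes[[k]]
    if (!is.null(old) && !identical(old, attributes[[k]]))
      g$audit[[length(g$audit) + 1L]] <-
        list(concept = cid, attribute = k, overwritten = old, source = source)
    con$attributes[[k]] <- attributes[[k]]
  }
  con$provenance <- unique(c(con$provenance, source))
  con$evidence <- unique(c(con$evidence, evidence))
  g$concepts[[key]] <- con
  invisible(cid)
}

# Merge a set of same-class concepts into the lowest-id member, rewiring
# all relations and deduplicating any that become identical triples.
# Self-loop `equal` relations produced by the rewiring are dropped.
# Returns the representative id. Shared by upsert_concept (accession
# bridging) and collapse_equal (components of the equal subgraph).
merge_concepts <- function(g, ids) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) < 2) return(ids[1])
  classes <- unique(vapply(ids, function(i) g$concepts[[as.character(i)]]$class,
                           character(1)))
  if (length(classes) > 1)
    graph_error("cannot merge concepts of different classes: %s",
                paste(classes, collapse = ", "))
  rep_id <- ids[1]
  rep_key <- as.character(rep_id)
  rep_con <- g$concepts[[rep_key]]
  for (oid in ids[-1]) {
    okey <- as.character(oid)
    ocon <- g$concepts[[okey]]
    unindex_concept(g, ocon)
    # accession union
    have <- vapply(rep_con$accessions,
                   function(a) idx_key(a$namespace, a$value), character(1))
    for (a in ocon$accessions) {
      k <- idx_key(a$namespace, a$value)
      if (!(k %in% have)) {
        rep_con$accessions <- c(rep_con$accessions, list(a))
        have <- c(have, k)
      }
    }
    # name union; the representative keeps its preferred name, others demote
    if (nrow(ocon$names)) {
      onames <- ocon$names
      if (any(rep_con$names$preferred)) onames$preferred <- FALSE
      new <- onames[!(onames$name %in% rep_con$names$name), , drop = FALSE]
      if (nrow(new)) {
        if (any(rep_con$names$preferred)) new$preferred <- FALSE
        rep_con$names <- rbind(rep_con$names, new)
        if (sum(rep_con$names$preferred) > 1) {
          first <- which(rep_con$names$preferred)[1]
          rep_con$names$preferred <- seq_len(nrow(rep_con$names)) == first
        }
      }
    }
    # attributes: last-writer-wins in ascending id order, with audit
    for (k in names(ocon$attributes)) {
      old <- rep_con$attributes[[k]]
      if (!is.null(old) && !identical(old, ocon$attributes[[k]]))
        g$audit[[length(g$audit) + 1L]] <-
          list(concept = rep_id, attribute = k, overwritten = old,
               source = paste0("merge:", oid))
      rep_con$attributes[[k]] <- ocon$attributes[[k]]
    }
    rep_con$provenance <- unique(c(rep_con$provenance, ocon$provenance))
    rep_con$evidence <- unique(c(rep_con$evidence, ocon$evidence))
    # rewire relations touching oid
    for (rid in idx_get(g$adj, okey)) {
      rkey <- as.character(rid)
      rel <- g$relations[[rkey]]
      if (is.null(rel)) next
      old_key <- idx_key(rel$from, rel$to, rel$type)
      from <- if (rel$from == oid) rep_id else rel$from
      to <- if (rel$to == oid) rep_id else rel$to
      if (rel$from != oid) idx_remove(g$adj, as.character(rel$from), rid)
      if (rel$to != oid && rel$to != rel$from) idx_remove(g$adj, as.character(rel$to), rid)
      if (!is.null(g$rel_index[[old_key]]) && g$rel_index[[old_key]] == rid)
        rm(list = old_key, envir = g$rel_index)
      rm(list = rkey, envir = g$relations)
      if (from == to && rel$type == "equal") next  # degenerate after merge
      ft <- rel_canon(g, from, to, rel$type)
      new_key <- idx_key(ft[1], ft[2], rel$type)
      ex <- g$rel_index[[new_key]]
      if (!is.null(ex)) {
        ekey <- as.character(ex)
        r0 <- g$relations[[ekey]]
        for (k in names(rel$attributes)) r0$attributes[[k]] <- rel$attributes[[k]]
        r0$provenance <- unique(c(r0$provenance, rel$provenance))
        r0$evidence <- unique(c(r0$evidence, rel$evidence))
        g$relations[[ekey]] <- r0
      } else {
        rel$from <- ft[1]; rel$to <- ft[2]
        g$relations[[rkey]] <- rel
        g$rel_index[[new_key]] <- rid
        idx_add(g$adj, as.character(ft[1]), rid)
        if (ft[2] != ft[1]) idx_add(g$adj, as.character(ft[2]), rid)
      }
    }
    if (exists(okey, envir = g$adj, inherits = FALSE)) rm(list = okey, envir = g$adj)
    rm(list = okey, envir = g$concepts)
  }
  g$concepts[[rep_key]] <- rep_con
  # reindex the representative (accessions/names gained from the merged set)
  unindex_concept(g, rep_con); index_concept(g, rep_con)
  rep_id
}

#' Merge-overwrite audit trail
#'
#' When concept merging (during [upsert_concept()] or [collapse_equal()])
#' overwrites an attribute value, the overwritten value is appended here.
#'
#' @param g a `kg`.
#' @return list of records (concept, attribute, overwritten, source).
#' @export
kg_audit <- function(g) g$audit

rel_canon <- function(g, from, to, type) {
  if (is_symmetric_type(g$meta, type) && to < from) c(to, from) else c(from, to)
}

#' Add (or merge into) a relation
#'
#' Relations are deduplicated on the (from, to, type) triple: adding an
#' existing triple merges attributes, provenance and evidence into the
#' stored relation and returns its id. For relation types flagged symmetric
#' in the meta-model (`equal`, `ortholog`, ...), `(a, b)` and `(b, a)` are
#' the same relation.
#'
#' @inheritParams upsert_concept
#' @param from,to concept ids (must exist).
#' @param type relation-type id.
#' @return The relation id (integer).
#' @export
add_relation <- function(g, from, to, type, attributes = list(),
                         source = "UC", evidence = "IMPD") {
  stopifnot(inherits(g, "kg"))
  if (!meta_has(g$meta, "relation_types", type))
    meta_error("unknown relation type '%s'", type)
  if (is.null(g$concepts[[as.character(from)]]))
    graph_error("relation endpoint %s does not exist", from)
  if (is.null(g$concepts[[as.character(to)]]))
    graph_error("relation endpoint %s does not exist", to)
  check_attributes(g, attributes)
  ensure_source(g, source)
  ensure_evidence(g, evidence)

  ft <- rel_canon(g, from, to, type)
  key <- idx_key(ft[1], ft[2], type)
  rid <- g$rel_index[[key]]
  if (!is.null(rid)) {
    rkey <- as.character(rid)
    rel <- g$relations[[rkey]]
    for (k in names(attributes)) rel$attributes[[k]] <- attributes[[k]]
    rel$provenance <- unique(c(rel$provenance, source))
    rel$evidence <- unique(c(rel$evidence, evidence))
    g$relations[[rkey]] <- rel
    return(rid)
  }
  rid <- g$next_rid
  g$next_rid <- g$next_rid + 1L
  g$relations[[as.character(rid)]] <-
    list(id = rid, from = ft[1], to = ft[2], type = type,
         attributes = attributes, provenance = source,
         evidence = unique(evidence))
  g$rel_index[[key]] <- rid
  idx_add(g$adj, as.character(ft[1]), rid)
  if (ft[2] != ft[1]) idx_add(g$adj, as.character(ft[2]), rid)
  rid
}

#' Graph accessors
#'
#' @param g a `kg`.
#' @param id concept or relation id.
#' @return `kg_concept()`/`kg_relation()` return the stored record (a list);
#'   `kg_concept_ids()`/`kg_relation_ids()` sorted integer ids;
#'   `kg_concept_count()`/`kg_relation_count()` counts;
#'   `kg_find_accession()` the ids of concepts holding the accession;
#'   `kg_find_name()` the ids of concepts bearing the (case-folded) name;
#'   `kg_attr()` one attribute value or `NULL`.
#' @export
kg_concept <- function(g, id) {
  con <- g$concepts[[as.character(id)]]
  if (is.null(con)) graph_error("no concept with id %s", id)
  con
}

#' @rdname kg_concept
#' @export
kg_relation <- function(g, id) {
  rel <- g$relations[[as.character(id)]]
  if (is.null(rel)) graph_error("no relation with id %s", id)
  rel
}

#' @rdname kg_concept
#' @export
kg_concept_ids <- function(g) sort(as.integer(ls(g$concepts)))

#' @rdname kg_concept
#' @export
kg_relation_ids <- function(g) sort(as.integer(ls(g$relations)))

#' @rdname kg_concept
#' @export
kg_concept_count <- function(g) length(ls(g$concepts))

#' @rdname kg_concept
#' @export
kg_relation_count <- function(g) length(ls(g$relations))

#' @rdname kg_concept
#' @param namespace,value accession components.
#' @export
kg_find_accession <- function(g, namespace, value)
  idx_get(g$acc_index, idx_key(namespace, value))

#' @rdname kg_concept
#' @param name concept name (matching is case-folded, whitespace-collapsed).
#' @export
kg_find_name <- function(g, name) idx_get(g$name_index, norm_name(name))

#' @rdname kg_concept
#' @param attribute attribute-name id.
#' @export
kg_attr <- function(g, id, attribute) kg_concept(g, id)$attributes[[attribute]]

#' @rdname kg_concept
#' @export
kg_preferred_name <- function(g, id) {
  nm <- kg_concept(g, id)$names
  if (nrow(nm) == 0) return(NA_character_)
  if (any(nm$preferred)) nm$name[nm$preferred][1] else nm$name[1]
}

#' Union of knowledge graphs
#'
#' Copies the concepts and relations of `...` into `g` with fresh ids and
#' **no** merging: cross-network entity resolution is the explicit
#' [accession_map()] + [collapse_equal()] path. Data sources and evidence
#' types of the incoming graphs are registered in `g`'s meta-model.
#'
#' @param g destination `kg` (mutated).
#' @param ... further `kg` objects.
#' @return `g`, invisibly.
#' @export
kg_union <- function(g, ...) {
  for (h in list(...)) {
    stopifnot(inherits(h, "kg"))
    idmap <- new.env(parent = emptyenv())
    for (cid in kg_concept_ids(h)) {
      con <- h$concepts[[as.character(cid)]]
      for (s in con$provenance) ensure_source(g, s)
      ensure_evidence(g, con$evidence)
      ncid <- g$next_cid
      g$next_cid <- g$next_cid + 1L
      ncon <- con
      ncon$id <- ncid
      g$concepts[[as.character(ncid)]] <- ncon
      index_concept(g, ncon)
      idmap[[as.character(cid)]] <- ncid
    }
    for (rid in kg_relation_ids(h)) {
      rel <- h$relations[[as.character(rid)]]
      for (s in rel$provenance) ensure_source(g, s)
      ensure_evidence(g, rel$evidence)
      from <- idmap[[as.character(rel$from)]]
      to <- idmap[[as.character(rel$to)]]
      ft <- rel_canon(g, from, to, rel$type)
      key <- idx_key(ft[1], ft[2], rel$type)
      ex <- g$rel_index[[key]]
      if (!is.null(ex)) {
        rk <- as.character(ex)
        r0 <- g$relations[[rk]]
        for (k in names(rel$attributes)) r0$attributes[[k]] <- rel$attributes[[k]]
        r0$provenance <- unique(c(r0$provenance, rel$provenance))
        r0$evidence <- unique(c(r0$evidence, rel$evidence))
        g$relations[[rk]] <- r0
      } else {
        nrid <- g$next_rid
        g$next_rid <- g$next_rid + 1L
        nrel <- rel
        nrel$id <- nrid; nrel$from <- ft[1]; nrel$to <- ft[2]
        g$relations[[as.character(nrid)]] <- nrel
        g$rel_index[[key]] <- nrid
        idx_add(g$adj, as.character(ft[1]), nrid)
        if (ft[2] != ft[1]) idx_add(g$adj, as.character(ft[2]), nrid)
      }
    }
  }
  invisible(g)
}

#' Induced subgraph
#'
#' Builds a new graph over the given concepts, keeping the relations whose
#' two endpoints are both retained (optionally restricted to `relation_ids`).
#' Concept and relation ids are preserved.
#'
#' @param g a `kg`.
#' @param concept_ids integer ids to retain.
#' @param relation_ids optional relation ids to retain (default: all whose
#'   endpoints are retained).
#' @return a new `kg`.
#' @export
kg_subgraph <- function(g, concept_ids, relation_ids = NULL) {
  h <- kg_new(g$meta)
  keep <- as.character(sort(unique(as.integer(concept_ids))))
  for (k in keep) {
    con <- g$concepts[[k]]
    if (is.null(con)) graph_error("no concept with id %s", k)
    h$concepts[[k]] <- con
    index_concept(h, con)
  }
  rids <- if (is.null(relation_ids)) kg_relation_ids(g)
          else sort(unique(as.integer(relation_ids)))
  for (rid in rids) {
    rel <- g$relations[[as.character(rid)]]
    if (is.null(rel)) next
    if (as.character(rel$from) %in% keep && as.character(rel$to) %in% keep) {
      h$relations[[as.character(rid)]] <- rel
      h$rel_index[[idx_key(rel$from, rel$to, rel$type)]] <- rid
      idx_add(h$adj, as.character(rel$from), rid)
      if (rel$to != rel$from) idx_add(h$adj, as.character(rel$to), rid)
    }
  }
  h$next_cid <- g$next_cid
  h$next_rid <- g$next_rid
  h
}

#' Metagraph summary
#'
#' Schema-level summary of a knowledge network: instance counts per concept
#' class and per (source class, relation type, target class) triple. Only
#' classes and triples with at least one instance appear. Node counts sum
#' to the concept count and edge counts to the relation count.
#'
#' @param g a `kg`.
#' @return list with `nodes` (named integer vector, by class id) and
#'   `edges` (data.frame `from_class`, `type`, `to_class`, `count`),
#'   of class `gsknet_metagraph`.
#' @export
kg_metagraph <- function(g) {
  classes <- vapply(ls(g$concepts), function(k) g$concepts[[k]]$class, character(1))
  nodes <- if (length(classes)) {
    tb <- table(classes)
    setNames(as.integer(tb), names(tb))
  } else setNames(integer(0), character(0))
  rids <- ls(g$relations)
  if (length(rids)) {
    trip <- vapply(rids, function(k) {
      rel <- g$relations[[k]]
      idx_key(g$concepts[[as.character(rel$from)]]$class, rel$type,
              g$concepts[[as.character(rel$to)]]$class)
    }, character(1))
    tb <- table(trip)
    parts <- do.call(rbind, strsplit(names(tb), .SEP, fixed = TRUE))
    edges <- data.frame(from_class = parts[, 1], type = parts[, 2],
                        to_class = parts[, 3], count = as.integer(tb),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from_class, edges$type, edges$to_class), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from_class = character(0), type = character(0),
                        to_class = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes[order(names(nodes))], edges = edges),
            class = "gsknet_metagraph")
}

#' @export
print.gsknet_metagraph <- function(x, ...) {
  cat(sprintf("<metagraph: %d classes / %d concepts, %d edge types / %d relations>\n",
              length(x$nodes), sum(x$nodes), nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<knowledge graph: %d concepts, %d relations>\n",
              kg_concept_count(x), kg_relation_count(x)))
  invisible(x)
}
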