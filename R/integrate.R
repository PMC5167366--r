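#' Accession-based mapping
#'
#' Creates a relation of type `equal` between every pair of distinct
#' concepts of the same class that share a non-ambiguous accession. This is
#' the primary way independent parsed networks are interconnected after a
#' [kg_union()]; the `equal` relations are then resolved by
#' [collapse_equal()]. Ambiguous accessions never drive mapping.
#'
#' @param g a `kg` (mutated in place).
#' @param classes optional character vector restricting the concept classes
#'   considered (default: all).
#' @param namespaces optional character vector restricting the accession
#'   namespaces considered (default: all).
#' @return number of `equal` relations added.
#' @export
accession_map <- function(g, classes = NULL, namespaces = NULL) {
  stopifnot(inherits(g, "kg"))
  added <- 0L
  for (key in ls(g$acc_index)) {
    ids <- g$acc_index[[key]]
    if (length(ids) < 2) next
    ns <- strsplit(key, .SEP, fixed = TRUE)[[1]][1]
    if (!is.null(namespaces) && !(ns %in% namespaces)) next
    # drop holders for which this accession is flagged ambiguous
    ok <- vapply(ids, function(id) {
      con <- g$concepts[[as.character(id)]]
      if (!is.null(classes) && !(con$class %in% classes)) return(FALSE)
      for (a in con$accessions)
        if (idx_key(a$namespace, a$value) == key) return(!a$ambiguous)
      FALSE
    }, logical(1))
    ids <- ids[ok]
    if (length(ids) < 2) next
    cls <- vapply(ids, function(id) g$concepts[[as.character(id)]]$class, character(1))
    for (cl in unique(cls)) {
      members <- sort(ids[cls == cl])
      if (length(members) < 2) next
      for (i in seq_len(length(members) - 1L))
        for (j in seq((i + 1L), length(members))) {
          before <- kg_relation_count(g)
          add_relation(g, members[i], members[j], "equal",
                       source = "UC", evidence = "ACC")
          if (kg_relation_count(g) > before) added <- added + 1L
        }
    }
  }
  added
}

#' Name-based mapping
#'
#' Creates `equal` relations between same-class concepts sharing a
#' normalised name or synonym (case-folded, whitespace-collapsed). Names
#' shorter than `min_len` characters never match: short symbols are too
#' ambiguous to identify an entity.
#'
#' @inheritParams accession_map
#' @param min_len minimum (normalised) name length considered, default 3.
#' @return number of `equal` relations added.
#' @export
name_map <- function(g, classes = NULL, min_len = 3) {
  stopifnot(inherits(g, "kg"))
  added <- 0L
  for (key in ls(g$name_index)) {
    if (nchar(key) < min_len) next
    ids <- g$name_index[[key]]
    if (length(ids) < 2) next
    cls <- vapply(ids, function(id) g$concepts[[as.character(id)]]$class, character(1))
    keep <- if (is.null(classes)) rep(TRUE, length(ids)) else cls %in% classes
    ids <- ids[keep]; cls <- cls[keep]
    for (cl in unique(cls)) {
      members <- sort(ids[cls == cl])
      if (length(members) < 2) next
      for (i in seq_len(length(members) - 1L))
        for (j in seq((i + 1L), length(members))) {
          before <- kg_relation_count(g)
          add_relation(g, members[i], members[j], "equal",
                       source = "UC", evidence = "NAM")
          if (kg_relation_count(g) > before) added <- added + 1L
        }
    }
  }
  added
}

#' Gene-QTL co-location mapping
#'
#' Links located concepts of `subject_class` (default Gene) to located
#' concepts of `region_class` (default QTL) whose intervals overlap
#' (closed-interval intersection non-empty) on the same chromosome, in the
#' same map unit (bp or cM) and for the same organism. Each concept may
#' carry a physical (`Location`) and/or a genetic-map (`GenMapLocation`)
#' location; all unit-compatible combinations are tested, so datasets on
#' different maps never co-locate spuriously.
#'
#' @param g a `kg` (mutated).
#' @param subject_class class of the located subjects (relation source).
#' @param region_class class of the covering regions (relation target).
#' @param type relation type to create, default `"colocated"`.
#' @param evidence evidence-type id for the created relations.
#' @return number of relations added.
#' @export
colocation_map <- function(g, subject_class = "Gene", region_class = "QTL",
                           type = "colocated", evidence = "COL") {
  overlap_link(g, subject_class, region_class, window = 0,
               subject_point = FALSE, type = type, evidence = evidence)
}

#' SNP-gene proximity mapping
#'
#' Links point-located concepts of `subject_class` (default SNP) to
#' interval-located concepts of `target_class` (default Gene) when the
#' point lies within the interval extended by `window` map units on both
#' sides. Same chromosome/unit/taxid rules as [colocation_map()].
#'
#' @inheritParams colocation_map
#' @param target_class class of the interval-located targets.
#' @param window symmetric extension of target intervals (same unit as the
#'   locations; default 0, i.e. within the interval itself).
#' @return number of `in_proximity` relations added.
#' @export
proximity_map <- function(g, subject_class = "SNP", target_class = "Gene",
                          window = 0, type = "in_proximity", evidence = "COL") {
  overlap_link(g, subject_class, target_class, window = window,
               subject_point = TRUE, type = type, evidence = evidence)
}

# shared interval-overlap engine; groups locations by (chromosome, unit,
# taxid) and finds overlaps with IRanges on a fixed-precision integer grid
# (cM values are scaled by 1e4 to permit fractional coordinates)
overlap_link <- function(g, subject_class, target_class, window,
                         subject_point, type, evidence) {
  stopifnot(inherits(g, "kg"))
  subj <- gather_locations(g, subject_class)
  targ <- gather_locations(g, target_class)
  if (length(subj) == 0 || length(targ) == 0) return(0L)
  scale_coord <- function(x, unit) as.integer(round(x * if (unit == "cM") 1e4 else 1))
  frames <- function(entries) vapply(entries, function(e) loc_frame(e$loc), character(1))
  sf <- frames(subj); tf <- frames(targ)
  added <- 0L
  seen <- new.env(parent = emptyenv())
  for (fr in intersect(unique(sf), unique(tf))) {
    ss <- subj[sf == fr]; ts <- targ[tf == fr]
    unit <- ss[[1]]$loc$unit
    w <- scale_coord(window, unit)
    sr <- IRanges::IRanges(
      start = vapply(ss, function(e) scale_coord(e$loc$begin, unit), integer(1)),
      end   = vapply(ss, function(e) scale_coord(e$loc$end, unit), integer(1)))
    tr <- IRanges::IRanges(
      start = vapply(ts, function(e) scale_coord(e$loc$begin, unit), integer(1)) - w,
      end   = vapply(ts, function(e) scale_coord(e$loc$end, unit), integer(1)) + w)
    hits <- IRanges::findOverlaps(sr, tr)
    for (h in seq_along(hits)) {
      si <- ss[[S4Vectors::queryHits(hits)[h]]]$id
      ti <- ts[[S4Vectors::subjectHits(hits)[h]]]$id
      if (si == ti) next
      k <- idx_key(si, ti)
      if (!is.null(seen[[k]])) next
      seen[[k]] <- TRUE
      before <- kg_relation_count(g)
      add_relation(g, si, ti, type, source = "UC", evidence = evidence)
      if (kg_relation_count(g) > before) added <- added + 1L
    }
  }
  added
}

#' External2GO cross-references
#'
#' Reads a standard external2go mapping file (lines of the form
#' `InterPro:IPR003657 WRKY domain > GO:DNA binding ; GO:0003700`) and adds
#' `cross_reference` relations between the named external concepts (looked
#' up by accession, e.g. Protein Domain concepts with InterPro accessions)
#' and GO-term concepts, wherever both ends exist in the graph. Lines whose
#' either end is absent are counted as unmatched; malformed lines are
#' skipped with a warning.
#'
#' @param g a `kg` (mutated).
#' @param path external2go mapping file.
#' @return list with `added` (relation count) and `unmatched` (line count).
#' @export
external2go_map <- function(g, path) {
  stopifnot(inherits(g, "kg"))
  lines <- read_all_lines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  added <- 0L; unmatched <- 0L; malformed <- 0L
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+):(\\S+)[^>]*>.*;\\s*(GO:\\d{7})\\s*$", ln))[[1]]
    if (length(m) != 4) { malformed <- malformed + 1L; next }
    ext <- kg_find_accession(g, m[2], paste0(m[2], ":", m[3]))
    if (length(ext) == 0) ext <- kg_find_accession(g, m[2], m[3])
    if (length(ext) == 0) ext <- kg_find_accession(g, toupper(m[2]), m[3])
    go <- kg_find_accession(g, "GO", m[4])
    if (length(ext) == 0 || length(go) == 0) { unmatched <- unmatched + 1L; next }
    for (e in ext) for (t in go) {
      before <- kg_relation_count(g)
      add_relation(g, e, t, "cross_reference", source = "UC", evidence = "E2G")
      if (kg_relation_count(g) > before) added <- added + 1L
    }
  }
  if (malformed > 0)
    warning(sprintf("skipped %d malformed external2go line(s)", malformed))
  list(added = added, unmatched = unmatched)
}

#' Collapse equivalent concepts
#'
#' Resolves all `equal` relations: every connected component of the
#' equal-relation subgraph is merged into a single representative concept
#' (the lowest concept id in the component) whose accessions, names,
#' attributes, provenance and evidence are the union over the component.
#' All other relations are rewired to the representative, duplicates
#' merged, and the `equal` relations removed, so no entity occurs more than
#' once in the network afterwards. Components containing concepts of
#' different classes are rejected (not merged) and reported: equality
#' across classes is always an integration error.
#'
#' The operation is idempotent, conserves the multiset of provenance
#' entries over all concepts, and never loses accessions.
#'
#' @param g a `kg` (mutated).
#' @return list of class `gsknet_collapse_report`: `groups` (number of
#'   merged components), `concepts_removed`, `relations_removed`,
#'   `rejected` (list of id vectors of mixed-class components).
#' @export
collapse_equal <- function(g) {
  stopifnot(inherits(g, "kg"))
  c_before <- kg_concept_count(g)
  r_before <- kg_relation_count(g)
  eq <- Filter(Negate(is.null),
               lapply(ls(g$relations), function(k) {
                 rel <- g$relations[[k]]
                 if (rel$type == "equal") rel else NULL
               }))
  rejected <- list()
  groups <- 0L
  if (length(eq)) {
    verts <- unique(c(vapply(eq, `[[`, numeric(1), "from"),
                      vapply(eq, `[[`, numeric(1), "to")))
    edges <- cbind(match(vapply(eq, `[[`, numeric(1), "from"), verts),
                   match(vapply(eq, `[[`, numeric(1), "to"), verts))
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    comp <- igraph::components(ig)$membership
    for (ci in seq_len(max(comp))) {
      members <- sort(verts[which(comp == ci)])
      if (length(members) < 2) next
      classes <- unique(vapply(members, function(id)
        g$concepts[[as.character(id)]]$class, character(1)))
      if (length(classes) > 1) {
        rejected[[length(rejected) + 1L]] <- members
        next
      }
      merge_concepts(g, members)
      groups <- groups + 1L
    }
  }
  # drop any remaining equal relations inside accepted (now merged) groups;
  # merge_concepts already removed self-loop equals, so what is left are
  # equal relations of rejected components, which are kept
  structure(list(groups = groups,
                 concepts_removed = c_before - kg_concept_count(g),
                 relations_removed = r_before - kg_relation_count(g),
                 rejected = rejected),
            class = "gsknet_collapse_report")
}

#' @export
print.gsknet_collapse_report <- function(x, ...) {
  cat(sprintf("<collapse: %d group(s) merged, %d concept(s) and %d relation(s) removed, %d component(s) rejected>\n",
              x$groups, x$concepts_removed, x$relations_removed, length(x$rejected)))
  invisible(x)
}
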