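# plugin registry: how each declarative workflow step maps onto package
# operations. kind "parse" creates a graph (needs `out`), "union" combines
# labelled graphs, "transform" mutates a labelled graph, "export" writes it.
workflow_plugins <- function() {
  list(
    parse_fasta_gff3  = list(kind = "parse", required = c("gff3", "fasta", "taxid")),
    parse_obo         = list(kind = "parse", required = "path"),
    parse_gaf         = list(kind = "parse", required = "path"),
    parse_tabular     = list(kind = "parse", required = c("path", "spec")),
    parse_publications = list(kind = "parse", required = "path"),
    parse_uniprot_min = list(kind = "parse", required = "path"),
    union             = list(kind = "union", required = character(0)),
    accession_map     = list(kind = "transform", required = character(0)),
    name_map          = list(kind = "transform", required = character(0)),
    sequence_map      = list(kind = "transform", required = character(0)),
    colocation_map    = list(kind = "transform", required = character(0)),
    proximity_map     = list(kind = "transform", required = character(0)),
    external2go_map   = list(kind = "transform", required = "path"),
    collapse_equal    = list(kind = "transform", required = character(0)),
    textmine          = list(kind = "transform", required = c("gene_class", "term_class")),
    write_oxl         = list(kind = "export", required = "path"),
    write_json        = list(kind = "export", required = "path")
  )
}

#' Load a declarative integration workflow
#'
#' A workflow is an ordered list of steps, each naming a plugin (a package
#' operation), its parameters, and the graph label it reads
#' (`graph`)/creates (`out`)/combines (`inputs`). Workflows are the
#' reproducible description of a network build: a fixed seed and input
#' files fully determine every output byte. The file may be YAML (primary
#' form) or an XML document with the same structure (`<workflow seed=...>`
#' containing `<step plugin=... out=... graph=...>` elements whose
#' `<param name=...>` children hold scalar values, or YAML text when
#' `format="yaml"`).
#'
#' Validation happens before execution: unknown plugins, missing required
#' parameters and graph labels used before definition are all rejected.
#'
#' @param path workflow file (`.yaml`/`.yml` or `.xml`).
#' @return list of class `gsknet_workflow` with `seed`, `steps`,
#'   `base_dir` (directory of `path`; relative file parameters resolve
#'   against it).
#' @export
load_workflow <- function(path) {
  raw <- if (grepl("\\.xml$", path, ignore.case = TRUE))
    workflow_from_xml(path) else yaml::read_yaml(path)
  steps <- raw$steps
  if (is.null(steps) || length(steps) == 0)
    spec_error("workflow has no steps")
  plugins <- workflow_plugins()
  defined <- character(0)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (is.null(st$plugin))
      spec_error("step %d names no plugin", i)
    pl <- plugins[[st$plugin]]
    if (is.null(pl))
      spec_error("step %d: unknown plugin '%s'", i, st$plugin)
    miss <- setdiff(pl$required, names(st$params %||% list()))
    if (length(miss))
      spec_error("step %d (%s): missing required parameter(s) %s",
                 i, st$plugin, paste(miss, collapse = ", "))
    if (pl$kind == "parse") {
      if (is.null(st$out)) spec_error("step %d (%s): parse steps need 'out'", i, st$plugin)
      defined <- c(defined, st$out)
    } else if (pl$kind == "union") {
      if (is.null(st$out) || is.null(st$inputs))
        spec_error("step %d (union): needs 'inputs' and 'out'", i)
      undef <- setdiff(unlist(st$inputs), defined)
      if (length(undef))
        spec_error("step %d (union): undefined graph label(s) %s",
                   i, paste(undef, collapse = ", "))
      defined <- c(defined, st$out)
    } else {
      if (is.null(st$graph))
        spec_error("step %d (%s): needs a 'graph' label", i, st$plugin)
      if (!(st$graph %in% defined))
        spec_error("step %d (%s): undefined graph label '%s'", i, st$plugin, st$graph)
    }
  }
  structure(list(seed = raw$seed %||% 1L, steps = steps,
                 base_dir = dirname(normalizePath(path))),
            class = "gsknet_workflow")
}

workflow_from_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "workflow")
    parse_error("workflow XML root must be <workflow>")
  seed <- xml2::xml_attr(doc, "seed")
  steps <- lapply(xml2::xml_find_all(doc, "./step"), function(sn) {
    params <- list()
    for (pn in xml2::xml_find_all(sn, "./param")) {
      nm <- xml2::xml_attr(pn, "name")
      val <- xml2::xml_text(pn)
      if (identical(xml2::xml_attr(pn, "format"), "yaml"))
        val <- yaml::yaml.load(val)
      params[[nm]] <- val
    }
    st <- list(plugin = xml2::xml_attr(sn, "plugin"), params = params)
    for (f in c("out", "graph")) {
      v <- xml2::xml_attr(sn, f)
      if (!is.na(v)) st[[f]] <- v
    }
    inp <- xml2::xml_attr(sn, "inputs")
    if (!is.na(inp)) st$inputs <- strsplit(inp, ",")[[1]]
    st
  })
  list(seed = if (!is.na(seed)) as.integer(seed) else NULL, steps = steps)
}

#' Write a workflow back to YAML
#'
#' @param wf a `gsknet_workflow` (or the raw list form).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_workflow <- function(wf, path) {
  yaml::write_yaml(list(seed = wf$seed, steps = wf$steps), path)
  invisible(path)
}

spec_from_params <- function(p) {
  slot <- function(s) {
    if (is.null(s)) return(NULL)
    if (!is.null(s$attributes)) s$attributes <- as.list(s$attributes)
    s
  }
  table_spec(subject = slot(p$subject), object = slot(p$object),
             relation = p$relation, source = p$source %||% "UC",
             evidence = p$evidence %||% "IMPD", taxid = p$taxid)
}

#' Run an integration workflow
#'
#' Executes the steps of a [load_workflow()] specification in order,
#' keeping a registry of labelled graphs, and collects an integration log:
#' one record per step with its parameters, duration, concept/relation
#' counts before and after, the operation's return value and any warnings.
#' A step failure aborts the run with the partial log attached to the
#' error condition.
#'
#' @param wf a `gsknet_workflow`.
#' @param base_dir directory against which relative file parameters
#'   resolve (default: where the workflow file lives).
#' @return list with `graph` (the graph touched by the last step), `graphs`
#'   (named list of all labelled graphs) and `log` (a
#'   `gsknet_integration_log`).
#' @export
run_workflow <- function(wf, base_dir = wf$base_dir) {
  stopifnot(inherits(wf, "gsknet_workflow"))
  set.seed(wf$seed)
  plugins <- workflow_plugins()
  registry <- new.env(parent = emptyenv())
  log <- list()
  last_label <- NULL

  resolve <- function(p) {
    if (is.character(p) && length(p) == 1 && !grepl("^/", p) &&
        file.exists(file.path(base_dir, p))) file.path(base_dir, p) else p
  }

  for (i in seq_along(wf$steps)) {
    st <- wf$steps[[i]]
    pl <- plugins[[st$plugin]]
    params <- st$params %||% list()
    warnings <- character(0)
    t0 <- proc.time()[["elapsed"]]
    label <- st$out %||% st$graph
    gref <- if (!is.null(st$graph)) registry[[st$graph]] else NULL
    before <- if (!is.null(gref)) c(kg_concept_count(gref), kg_relation_count(gref)) else c(0L, 0L)

    result <- withCallingHandlers(
      tryCatch({
        switch(pl$kind,
          parse = {
            g <- switch(st$plugin,
              parse_fasta_gff3 = parse_fasta_gff3(resolve(params$gff3),
                                                  resolve(params$fasta),
                                                  params$taxid,
                                                  namespace = params$namespace %||% "ENSEMBL"),
              parse_obo = parse_obo(resolve(params$path), class = params$class),
              parse_gaf = parse_gaf(resolve(params$path)),
              parse_tabular = parse_tabular(resolve(params$path),
                                            spec_from_params(params$spec)),
              parse_publications = parse_publications(resolve(params$path)),
              parse_uniprot_min = parse_uniprot_min(resolve(params$path),
                                                    namespace = params$namespace %||% "UNIPROT"))
            registry[[st$out]] <- g
            list(value = kg_concept_count(g), graph = g)
          },
          union = {
            g <- kg_new()
            do.call(kg_union, c(list(g), lapply(unlist(st$inputs),
                                                function(l) registry[[l]])))
            registry[[st$out]] <- g
            list(value = kg_concept_count(g), graph = g)
          },
          transform = {
            g <- registry[[st$graph]]
            val <- switch(st$plugin,
              accession_map = accession_map(g, classes = unlist(params$classes),
                                            namespaces = unlist(params$namespaces)),
              name_map = name_map(g, classes = unlist(params$classes),
                                  min_len = params$min_len %||% 3),
              sequence_map = sequence_map(g,
                                          query_class = params$query_class %||% "Protein",
                                          subject_class = params$subject_class %||% "Protein",
                                          top_k = params$top_k %||% 10,
                                          min_score = params$min_score %||% 0),
              colocation_map = colocation_map(g,
                                              subject_class = params$subject_class %||% "Gene",
                                              region_class = params$region_class %||% "QTL"),
              proximity_map = proximity_map(g,
                                            subject_class = params$subject_class %||% "SNP",
                                            target_class = params$target_class %||% "Gene",
                                            window = params$window %||% 0),
              external2go_map = external2go_map(g, resolve(params$path))$added,
              collapse_equal = collapse_equal(g)$groups,
              textmine = {
                gd <- build_dictionary(g, params$gene_class,
                                       min_len = params$gene_min_len %||% 3,
                                       case_sensitive = TRUE)
                td <- build_dictionary(g, params$term_class,
                                       min_len = params$term_min_len %||% 3,
                                       case_sensitive = FALSE)
                as.integer(cooccurrence_map(g, gd, td))
              })
            list(value = val, graph = g)
          },
          export = {
            g <- registry[[st$graph]]
            path <- params$path
            if (!grepl("^/", path)) path <- file.path(base_dir, path)
            switch(st$plugin,
               write_oxl = write_oxl(g, path),
               write_json = write_json_graph(g, path))
            list(value = path, graph = g)
          })
      }, error = function(e) e),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })

    if (inherits(result, "error")) {
      stop(errorCondition(
        sprintf("workflow step %d (%s) failed: %s", i, st$plugin,
                conditionMessage(result)),
        class = c("gsknet_workflow_error", "gsknet_error", "error"),
        log = structure(log, class = "gsknet_integration_log")))
    }
    gref <- result$graph
    log[[i]] <- list(
      step = i, plugin = st$plugin, label = label,
      params = params,
      duration = round(proc.time()[["elapsed"]] - t0, 4),
      concepts_before = before[1], relations_before = before[2],
      concepts_after = kg_concept_count(gref),
      relations_after = kg_relation_count(gref),
      value = result$value, warnings = warnings)
    last_label <- label
  }
  graphs <- setNames(lapply(ls(registry), function(l) registry[[l]]), ls(registry))
  list(graph = registry[[last_label]],
       graphs = graphs,
       log = structure(log, class = "gsknet_integration_log"))
}

#' Write an integration log
#'
#' Emits the line-oriented text log plus a machine-readable JSON twin
#' (`<path>.json`).
#'
#' @param log a `gsknet_integration_log` from [run_workflow()].
#' @param path destination text file.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  lines <- vapply(log, function(r) {
    sprintf("step %d %-18s graph=%s %ds concepts %d->%d relations %d->%d value=%s%s",
            r$step, r$plugin, r$label %||% "-", round(r$duration),
            r$concepts_before, r$concepts_after,
            r$relations_before, r$relations_after,
            paste(format(r$value), collapse = ","),
            if (length(r$warnings)) paste0(" warnings=", length(r$warnings)) else "")
  }, character(1))
  write_lines_lf(lines, path)
  jsonlite::write_json(lapply(unclass(log), function(r) {
    r$params <- NULL  # params may hold nested specs; keep the JSON log flat
    r
  }), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.gsknet_integration_log <- function(x, ...) {
  cat(sprintf("<integration log: %d step(s)>\n", length(x)))
  for (r in x)
    cat(sprintf("  %2d. %-18s concepts %d->%d relations %d->%d\n",
                r$step, r$plugin, r$concepts_before, r$concepts_after,
                r$relations_before, r$relations_after))
  invisible(x)
}
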