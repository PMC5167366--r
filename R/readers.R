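#' Parse gene models and protein sequences into a Gene-Protein network
#'
#' Reads a GFF3 file of gene models and a protein FASTA and produces a
#' network of Gene and Protein concepts connected by `encodes` relations:
#' one Gene per `gene` feature (with chromosome, begin, end and taxid
#' attributes plus a physical-map `Location`), one Protein per FASTA
#' sequence (with an `AA` sequence attribute), and one `encodes` relation
#' per gene product. FASTA ids must match GFF3 mRNA feature ids; sequences
#' with no GFF3 counterpart yield a warning and an orphan Protein concept.
#' Feature types other than `gene`/`mRNA`/`CDS` are ignored (counted in a
#' single warning).
#'
#' @param gff3 path to a GFF3 file (plain or gzip).
#' @param fasta path to a protein FASTA file.
#' @param taxid taxonomy id stamped on every concept.
#' @param namespace accession namespace (data-source id) for gene and
#'   transcript identifiers.
#' @param source provenance data-source id.
#' @return a `kg` containing the Gene-Protein network.
#' @export
parse_fasta_gff3 <- function(gff3, fasta, taxid, namespace = "ENSEMBL",
                             source = namespace) {
  check_gff3_lines(gff3)
  feats <- rtracklayer::import(gff3, format = "gff3")
  g <- kg_new()
  ensure_source(g, namespace); ensure_source(g, source)

  types <- as.character(feats$type)
  ignored <- sum(!(types %in% c("gene", "mRNA", "CDS")))
  if (ignored > 0)
    warning(sprintf("ignored %d GFF3 feature(s) of unhandled types", ignored))

  gene_rows <- which(types == "gene")
  gene_ids <- integer(0)
  for (i in gene_rows) {
    gid <- feats$ID[i]
    loc <- genomic_location(as.character(GenomicRanges::seqnames(feats)[i]),
                            GenomicRanges::start(feats)[i],
                            GenomicRanges::end(feats)[i], "bp", taxid)
    nm <- if (!is.null(feats$Name)) feats$Name[i] else NA_character_
    cid <- upsert_concept(
      g, "Gene", accessions = list(acc(namespace, gid)),
      preferred_name = if (!is.na(nm)) nm else NULL,
      attributes = list(TAXID = as.character(taxid),
                        Chromosome = loc$chromosome,
                        BEGIN = as.integer(loc$begin), END = as.integer(loc$end),
                        Strand = as.character(GenomicRanges::strand(feats)[i]),
                        Location = loc),
      source = source)
    gene_ids[gid] <- cid
  }

  # transcript id -> parent gene id
  tx_parent <- character(0)
  for (i in which(types == "mRNA")) {
    parents <- unlist(feats$Parent[i])
    if (length(parents)) tx_parent[feats$ID[i]] <- parents[1]
  }

  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  orphans <- 0L
  for (j in seq_along(seqs)) {
    pid <- ids[j]
    prot <- upsert_concept(
      g, "Protein", accessions = list(acc(namespace, pid)),
      attributes = list(TAXID = as.character(taxid),
                        AA = as.character(seqs[[j]])),
      source = source)
    parent <- tx_parent[pid]
    if (!is.na(parent) && parent %in% names(gene_ids)) {
      add_relation(g, gene_ids[[parent]], prot, "encodes", source = source)
    } else {
      orphans <- orphans + 1L
    }
  }
  if (orphans > 0)
    warning(sprintf("%d protein sequence(s) had no GFF3 counterpart (kept as orphan Proteins)",
                    orphans))
  g
}

check_gff3_lines <- function(path) {
  lines <- read_all_lines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9]
  if (length(bad))
    parse_error("malformed GFF3 line %d: expected 9 tab-separated fields", bad[1])
  invisible(TRUE)
}

#' Parse an OBO ontology into a term network
#'
#' One concept per non-obsolete `[Term]` stanza (accession namespace taken
#' from the id prefix, e.g. `GO`/`TO`; the term name becomes the preferred
#' name and synonyms additional names), with `is_a`, `part_of` and
#' `regulates` relations between terms. Relations to dangling targets are
#' skipped with a warning.
#'
#' @param path OBO 1.2/1.4 file (plain or gzip).
#' @param class concept class for all terms, or `NULL` to map GO namespaces
#'   (`biological_process` -> BioProc, `molecular_function` -> MolFunc,
#'   `cellular_component` -> CelComp).
#' @param source provenance data-source id (default: id prefix of the first
#'   term).
#' @return a `kg` of ontology terms.
#' @export
parse_obo <- function(path, class = NULL, source = NULL) {
  lines <- read_all_lines(path)
  stanza_starts <- which(lines == "[Term]")
  terms <- list()
  for (s in stanza_starts) {
    e <- s + 1L
    while (e <= length(lines) && !startsWith(lines[e], "[")) e <- e + 1L
    block <- lines[s:(e - 1L)]
    term <- list(synonyms = character(0), is_a = character(0),
                 part_of = character(0), regulates = character(0),
                 obsolete = FALSE)
    for (ln in block) {
      if (!grepl(":", ln, fixed = TRUE)) next
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:", "", ln))
      val <- sub("\\s*!.*$", "", val)   # strip trailing comments
      if (key == "id") term$id <- val
      else if (key == "name") term$name <- val
      else if (key == "namespace") term$namespace <- val
      else if (key == "is_obsolete") term$obsolete <- val == "true"
      else if (key == "synonym") {
        m <- regmatches(val, regexpr('"[^"]*"', val))
        if (length(m)) term$synonyms <- c(term$synonyms, gsub('"', "", m))
      }
      else if (key == "is_a") term$is_a <- c(term$is_a, val)
      else if (key == "relationship") {
        parts <- strsplit(val, "[[:space:]]+")[[1]]
        if (length(parts) >= 2 && parts[1] %in% c("part_of", "regulates"))
          term[[parts[1]]] <- c(term[[parts[1]]], parts[2])
      }
    }
    if (!is.null(term$id)) terms[[term$id]] <- term
  }
  terms <- Filter(function(t) !t$obsolete, terms)

  go_class <- c(biological_process = "BioProc", molecular_function = "MolFunc",
                cellular_component = "CelComp")
  g <- kg_new()
  cids <- integer(0)
  for (t in terms) {
    ns <- sub(":.*$", "", t$id)
    if (is.null(source)) source <- ns
    ensure_source(g, ns); ensure_source(g, source)
    cls <- if (!is.null(class)) class
           else if (!is.null(t$namespace) && t$namespace %in% names(go_class))
             go_class[[t$namespace]]
           else meta_error("term %s has no namespace and no class was given", t$id)
    cids[t$id] <- upsert_concept(g, cls, accessions = list(acc(ns, t$id)),
                                 preferred_name = t$name,
                                 synonyms = t$synonyms, source = source)
  }
  skipped <- 0L
  for (t in terms) {
    for (type in c("is_a", "part_of", "regulates")) {
      for (target in t[[type]]) {
        if (!(target %in% names(cids))) { skipped <- skipped + 1L; next }
        add_relation(g, cids[[t$id]], cids[[target]], type, source = source)
      }
    }
  }
  if (skipped > 0)
    warning(sprintf("skipped %d ontology relation(s) with dangling targets", skipped))
  g
}

#' Parse a GO annotation (GAF 2.x) file
#'
#' Produces annotated-entity concepts (class Gene or Protein according to
#' the DB-object-type column) linked to GO-term stub concepts. The aspect
#' column selects the relation type: P -> `participates_in`,
#' F -> `has_function`, C -> `located_in`; the GAF evidence code is
#' recorded as relation evidence. Rows qualified with NOT are skipped.
#' GO stubs carry only their accession; full term information arrives by
#' mapping and collapsing against an OBO-parsed network.
#'
#' @param path GAF 2.x file (tab-separated, `!` comments).
#' @return a `kg`.
#' @export
parse_gaf <- function(path) {
  lines <- read_all_lines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  aspect_rel <- c(P = "participates_in", F = "has_function", C = "located_in")
  aspect_class <- c(P = "BioProc", F = "MolFunc", C = "CelComp")
  type_class <- c(gene = "Gene", protein = "Protein")
  g <- kg_new()
  ensure_source(g, "GO")
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 13)
      parse_error("GAF line %d has %d fields; at least 13 required", i, length(f))
    qualifier <- f[4]
    if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
    aspect <- f[9]
    if (!(aspect %in% names(aspect_rel)))
      parse_error("GAF line %d: unknown aspect code '%s'", i, aspect)
    obj_type <- tolower(f[12])
    if (!(obj_type %in% names(type_class)))
      parse_error("GAF line %d: unmapped DB object type '%s'", i, f[12])
    db <- f[1]
    ensure_source(g, db)
    taxon <- sub("^taxon:", "", strsplit(f[13], "\\|")[[1]][1])
    entity <- upsert_concept(g, type_class[[obj_type]],
                             accessions = list(acc(db, f[2])),
                             preferred_name = if (nzchar(f[3])) f[3] else NULL,
                             attributes = list(TAXID = taxon),
                             source = db)
    go_stub <- upsert_concept(g, aspect_class[[aspect]],
                              accessions = list(acc("GO", f[5])),
                              source = "GO")
    ensure_evidence(g, f[7])
    add_relation(g, entity, go_stub, aspect_rel[[aspect]],
                 source = db, evidence = f[7])
  }
  g
}

#' Declarative tabular import specification
#'
#' Describes how the columns of a TSV file map onto concepts, attributes
#' and one optional relation, so arbitrary tabular datasets (SNP tables,
#' ortholog lists, domain assignments, QTL tables, ...) can be imported
#' without a dedicated parser. Within one parse, repeated accessions merge
#' into a single concept (see [upsert_concept()]).
#'
#' Each of `subject` and `object` is a list with elements:
#' `class` (concept class id), `accession_col`, `namespace`, and optionally
#' `name_col`, `attributes` (named list mapping attribute-name ids to
#' column names) and `location` (list with `attribute`, `chromosome_col`,
#' `begin_col`, optional `end_col`, `unit`, and optional `taxid`).
#'
#' @param subject binding for the subject concept of each row (required).
#' @param object optional binding for the object concept.
#' @param relation optional relation-type id connecting subject -> object.
#' @param source provenance data-source id.
#' @param evidence evidence-type id.
#' @param taxid optional taxonomy id stamped on all concepts.
#' @return list of class `gsknet_table_spec`.
#' @export
table_spec <- function(subject, object = NULL, relation = NULL,
                       source = "UC", evidence = "IMPD", taxid = NULL) {
  check_slot <- function(slot, nm) {
    if (is.null(slot$class) || is.null(slot$accession_col) || is.null(slot$namespace))
      spec_error("table spec %s binding needs class, accession_col and namespace", nm)
  }
  check_slot(subject, "subject")
  if (!is.null(relation) && is.null(object))
    spec_error("table spec declares a relation but no object binding")
  if (!is.null(object)) check_slot(object, "object")
  structure(list(subject = subject, object = object, relation = relation,
                 source = source, evidence = evidence, taxid = taxid),
            class = "gsknet_table_spec")
}

spec_columns <- function(slot) {
  cols <- c(slot$accession_col, slot$name_col,
            unlist(slot$attributes, use.names = FALSE))
  if (!is.null(slot$location))
    cols <- c(cols, slot$location$chromosome_col, slot$location$begin_col,
              slot$location$end_col)
  cols
}

#' Import a tabular (TSV) dataset
#'
#' Creates concepts (and optionally a relation) for every data row of a
#' tab-separated file with a header, as described by a [table_spec()].
#' Rows whose subject (or object) accession cell is empty are skipped with
#' a warning.
#'
#' @param path TSV file with a header row (plain or gzip).
#' @param spec a [table_spec()].
#' @return a `kg`.
#' @export
parse_tabular <- function(path, spec) {
  stopifnot(inherits(spec, "gsknet_table_spec"))
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  needed <- unique(c(spec_columns(spec$subject),
                     if (!is.null(spec$object)) spec_columns(spec$object)))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    spec_error("table lacks bound column(s): %s", paste(missing, collapse = ", "))

  g <- kg_new()
  ensure_source(g, spec$source)
  ensure_evidence(g, spec$evidence)
  skipped <- 0L

  build_slot <- function(slot, row) {
    accession <- trimws(row[[slot$accession_col]])
    if (!nzchar(accession)) return(NULL)
    attrs <- list()
    if (!is.null(spec$taxid)) attrs$TAXID <- as.character(spec$taxid)
    for (an in names(slot$attributes)) {
      raw <- row[[slot$attributes[[an]]]]
      if (is.na(raw) || !nzchar(raw)) next
      kind <- attr_kind(g$meta, an)
      attrs[[an]] <- switch(kind,
        integer = as.integer(raw), decimal = as.numeric(raw), raw)
    }
    if (!is.null(slot$location)) {
      lb <- slot$location
      begin <- as.numeric(row[[lb$begin_col]])
      end <- if (!is.null(lb$end_col)) as.numeric(row[[lb$end_col]]) else begin
      attrs[[lb$attribute %||% "Location"]] <-
        genomic_location(row[[lb$chromosome_col]], begin, end,
                         lb$unit %||% "bp",
                         lb$taxid %||% spec$taxid %||% "0")
    }
    nm <- if (!is.null(slot$name_col)) trimws(row[[slot$name_col]]) else NULL
    upsert_concept(g, slot$class,
                   accessions = list(acc(slot$namespace, accession)),
                   preferred_name = if (!is.null(nm) && nzchar(nm)) nm else NULL,
                   attributes = attrs, source = spec$source,
                   evidence = spec$evidence)
  }

  for (i in seq_len(nrow(df))) {
    row <- as.list(df[i, , drop = FALSE])
    subj <- build_slot(spec$subject, row)
    if (is.null(subj)) { skipped <- skipped + 1L; next }
    if (!is.null(spec$object)) {
      obj <- build_slot(spec$object, row)
      if (is.null(obj)) { skipped <- skipped + 1L; next }
      if (!is.null(spec$relation))
        add_relation(g, subj, obj, spec$relation,
                     source = spec$source, evidence = spec$evidence)
    }
  }
  if (skipped > 0)
    warning(sprintf("skipped %d row(s) with empty accession cells", skipped))
  g
}

#' Parse publication records
#'
#' Accepts either a minimal Medline-like XML document (`<PubmedArticle>`
#' records with `PMID`, `ArticleTitle` and `AbstractText` descendants) or
#' a 3-column TSV with header `pmid`, `title`, `abstract`. Produces
#' Publication concepts with accession namespace `PMID` and `Title` /
#' `Abstract` attributes (the abstract attribute is omitted when empty).
#' Duplicate PMIDs merge.
#'
#' @param path XML or TSV file.
#' @return a `kg` of Publication concepts.
#' @export
parse_publications <- function(path) {
  g <- kg_new()
  first <- trimws(paste(head(read_all_lines(path), 5), collapse = " "))
  if (startsWith(first, "<")) {
    doc <- xml2::read_xml(path)
    recs <- xml2::xml_find_all(doc, ".//PubmedArticle")
    for (r in recs) {
      pmid <- xml2::xml_text(xml2::xml_find_first(r, ".//PMID"))
      title <- xml2::xml_text(xml2::xml_find_first(r, ".//ArticleTitle"))
      abstract <- xml2::xml_find_first(r, ".//AbstractText")
      abstract <- if (inherits(abstract, "xml_missing")) "" else xml2::xml_text(abstract)
      add_publication(g, pmid, title, abstract)
    }
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE)
    need <- c("pmid", "title", "abstract")
    if (!all(need %in% names(df)))
      spec_error("publication TSV needs columns: %s", paste(need, collapse = ", "))
    for (i in seq_len(nrow(df)))
      add_publication(g, df$pmid[i], df$title[i], df$abstract[i])
  }
  g
}

add_publication <- function(g, pmid, title, abstract) {
  if (is.na(pmid) || !nzchar(pmid)) parse_error("publication record lacks a PMID")
  attrs <- list()
  if (!is.na(title) && nzchar(title)) attrs$Title <- title
  if (!is.na(abstract) && nzchar(abstract)) attrs$Abstract <- abstract
  upsert_concept(g, "Publication", accessions = list(acc("PMID", pmid)),
                 attributes = attrs, source = "PMID")
}

#' Parse a simplified reviewed-protein table
#'
#' A tabular stand-in for curated protein databases: one row per reviewed
#' protein, with columns `accession`, `name`, `taxid`, `sequence`,
#' `go_terms` (semicolon list of `ASPECT:GO:nnnnnnn` entries, aspect one of
#' P/F/C), `pmids` (semicolon list) and `phenotype` (free text, may be
#' empty). Produces Protein concepts, aspect-typed relations to GO stubs,
#' `published_in` relations to Publication stubs, and
#' `has_observed_phenotype` relations to Phenotype concepts (one per
#' distinct phenotype text). Malformed GO entries are skipped with a
#' warning.
#'
#' @param path TSV file with the header above.
#' @param namespace accession namespace for the proteins.
#' @return a `kg`.
#' @export
parse_uniprot_min <- function(path, namespace = "UNIPROT") {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE)
  need <- c("accession", "name", "taxid", "sequence", "go_terms", "pmids", "phenotype")
  if (!all(need %in% names(df)))
    spec_error("reviewed-protein table needs columns: %s", paste(need, collapse = ", "))
  aspect_rel <- c(P = "participates_in", F = "has_function", C = "located_in")
  aspect_class <- c(P = "BioProc", F = "MolFunc", C = "CelComp")
  g <- kg_new()
  ensure_source(g, namespace)
  phen_ids <- integer(0)
  bad_go <- 0L
  for (i in seq_len(nrow(df))) {
    attrs <- list(TAXID = df$taxid[i])
    if (nzchar(df$sequence[i])) attrs$AA <- df$sequence[i]
    prot <- upsert_concept(g, "Protein",
                           accessions = list(acc(namespace, df$accession[i])),
                           preferred_name = if (nzchar(df$name[i])) df$name[i] else NULL,
                           attributes = attrs, source = namespace)
    for (entry in strsplit(df$go_terms[i], ";", fixed = TRUE)[[1]]) {
      entry <- trimws(entry)
      if (!nzchar(entry)) next
      m <- regmatches(entry, regexec("^([PFC]):(GO:\\d{7})$", entry))[[1]]
      if (length(m) != 3) { bad_go <- bad_go + 1L; next }
      stub <- upsert_concept(g, aspect_class[[m[2]]],
                             accessions = list(acc("GO", m[3])), source = "GO")
      add_relation(g, prot, stub, aspect_rel[[m[2]]], source = namespace)
    }
    for (pmid in strsplit(df$pmids[i], ";", fixed = TRUE)[[1]]) {
      pmid <- trimws(pmid)
      if (!nzchar(pmid)) next
      pub <- upsert_concept(g, "Publication", accessions = list(acc("PMID", pmid)),
                            source = "PMID")
      add_relation(g, prot, pub, "published_in", source = namespace)
    }
    phen <- trimws(df$phenotype[i])
    if (nzchar(phen)) {
      key <- norm_name(phen)
      if (is.na(phen_ids[key])) {
        phen_ids[key] <- upsert_concept(g, "Phenotype", preferred_name = phen,
                                        source = namespace)
      }
      add_relation(g, prot, phen_ids[[key]], "has_observed_phenotype",
                   source = namespace)
    }
  }
  if (bad_go > 0)
    warning(sprintf("skipped %d malformed GO entr(y/ies)", bad_go))
  g
}
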