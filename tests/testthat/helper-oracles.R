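# Independent oracles and random-instance generators. Everything here is
# deliberately naive (loops, quadratic scans) and shares no code with the
# package implementation paths it checks.

## ---- union-find (collapse oracle) ------------------------------------------

uf_new <- function(ids) {
  parent <- as.list(setNames(ids, as.character(ids)))
  find <- function(x) {
    k <- as.character(x)
    while (parent[[k]] != x) { x <- parent[[k]]; k <- as.character(x) }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[as.character(max(ra, rb))]] <<- min(ra, rb)
  }
  list(find = function(x) find(x), union = union,
       groups = function() {
         roots <- vapply(ids, function(x) find(x), numeric(1))
         split(ids, roots)
       })
}

# expected partition of concept ids under equal edges, rejecting mixed-class
# components (mirrors the documented collapse semantics)
oracle_collapse_partition <- function(ids, classes, equal_edges) {
  uf <- uf_new(ids)
  if (nrow(equal_edges)) for (i in seq_len(nrow(equal_edges)))
    uf$union(equal_edges$from[i], equal_edges$to[i])
  groups <- uf$groups()
  lapply(groups, function(members) {
    cls <- unique(classes[as.character(members)])
    if (length(cls) > 1) as.list(members)    # rejected: stay singletons
    else list(sort(members))
  }) -> parts
  out <- list()
  for (p in parts) for (grp in p) out[[length(out) + 1L]] <- sort(unlist(grp))
  out[order(vapply(out, min, numeric(1)))]
}

## ---- brute-force interval overlap ------------------------------------------

# entries: list of list(id, chrom, begin, end, unit, taxid)
oracle_overlap_pairs <- function(subjects, targets, window = 0) {
  hits <- character(0)
  for (s in subjects) for (t in targets) {
    if (s$chrom != t$chrom || s$unit != t$unit || s$taxid != t$taxid) next
    if (s$id == t$id) next
    if (s$begin <= t$end + window && s$end >= t$begin - window)
      hits <- c(hits, paste(s$id, t$id))
  }
  sort(unique(hits))
}

## ---- textbook Smith-Waterman (three-state Gotoh, loops) --------------------

oracle_sw <- function(a, b, mat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(H[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(H[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   Ix[i, j], Iy[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

rand_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

## ---- naive same-sentence co-occurrence -------------------------------------

# abstracts: named list pmid -> text; dictionaries: named list surface -> ids.
# Returns data.frame(gene, term, pubs) using its own regex-based token match.
oracle_cooccurrence <- function(abstracts, gene_entries, term_entries,
                                split_fun) {
  tok <- function(x) {
    t <- regmatches(x, gregexpr("[A-Za-z0-9-]+", x))[[1]]
    t[t != "-"]
  }
  contains <- function(tokens, surface, fold) {
    st <- tok(surface)
    if (fold) { tokens <- tolower(tokens); st <- tolower(st) }
    L <- length(st)
    if (L == 0 || L > length(tokens)) return(FALSE)
    for (s in seq_len(length(tokens) - L + 1))
      if (all(tokens[s:(s + L - 1)] == st)) return(TRUE)
    FALSE
  }
  rows <- list()
  for (pmid in names(abstracts)) {
    for (sent in split_fun(abstracts[[pmid]])) {
      tokens <- tok(sent)
      genes <- unique(unlist(lapply(names(gene_entries), function(sf)
        if (contains(tokens, sf, fold = FALSE)) gene_entries[[sf]] else NULL)))
      if (length(genes) == 0) next
      terms <- unique(unlist(lapply(names(term_entries), function(sf)
        if (contains(tokens, sf, fold = TRUE)) term_entries[[sf]] else NULL)))
      for (ge in genes) for (te in terms)
        rows[[length(rows) + 1L]] <- data.frame(gene = ge, term = te,
                                                pmid = pmid)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = numeric(0), term = numeric(0), pubs = integer(0)))
  df <- do.call(rbind, rows)
  agg <- aggregate(pmid ~ gene + term, df, function(p) length(unique(p)))
  names(agg)[3] <- "pubs"
  agg[order(agg$gene, agg$term), , drop = FALSE]
}

## ---- random graph generator -------------------------------------------------

# a random but always-valid knowledge graph; equal edges only on request
rand_kg <- function(n_concepts = 30, n_relations = 40, p_equal = 0,
                    classes = c("Gene", "Protein", "QTL", "Trait", "Publication")) {
  g <- kg_new()
  sources <- c("ENSEMBL", "UNIPROT", "GRAMENE", "TAIR")
  types <- c("encodes", "ortholog", "control", "published_in",
             "interacts_with", "associated_with")
  for (i in seq_len(n_concepts)) {
    cls <- sample(classes, 1)
    accs <- list(acc(sample(sources, 1), sprintf("ACC%05d", i)))
    if (runif(1) < 0.3)
      accs <- c(accs, list(acc(sample(sources, 1), sprintf("ALT%05d", i),
                               ambiguous = runif(1) < 0.3)))
    attrs <- list(TAXID = sample(c("4565", "3702"), 1))
    if (runif(1) < 0.4) attrs$Score <- round(runif(1, 0, 100), 3)
    if (runif(1) < 0.3) attrs$CoCitations <- sample.int(50, 1)
    if (runif(1) < 0.3)
      attrs$Location <- genomic_location(sample(c("1A", "2B", "5H"), 1),
                                         b <- sample.int(10000, 1),
                                         b + sample.int(500, 1), "bp", "4565")
    upsert_concept(g, cls, accessions = accs,
                   preferred_name = if (runif(1) < 0.7) sprintf("name %d", i),
                   synonyms = if (runif(1) < 0.3) sprintf("syn-%d", i) else character(0),
                   attributes = attrs, source = sample(sources, 1))
  }
  ids <- kg_concept_ids(g)
  for (k in seq_len(n_relations)) {
    ft <- sample(ids, 2)
    add_relation(g, ft[1], ft[2], sample(types, 1),
                 attributes = if (runif(1) < 0.3) list(Score = round(runif(1), 3)) else list(),
                 source = sample(sources, 1))
  }
  if (p_equal > 0) {
    for (k in seq_len(ceiling(n_concepts * p_equal))) {
      pair <- sample(ids, 2)
      cls <- vapply(pair, function(i) kg_concept(g, i)$class, character(1))
      if (cls[1] == cls[2]) add_relation(g, pair[1], pair[2], "equal")
    }
  }
  g
}

## ---- canonical signatures for graph comparison ------------------------------

concept_signature <- function(con) {
  accs <- sort(vapply(con$accessions, function(a)
    paste(a$namespace, a$value, a$ambiguous), character(1)))
  nms <- con$names[order(con$names$name), , drop = FALSE]
  attrs <- con$attributes[sort(names(con$attributes))]
  list(class = con$class, accessions = accs,
       names = paste(nms$name, nms$preferred),
       attributes = attrs,
       provenance = sort(con$provenance), evidence = sort(con$evidence))
}

relation_signature <- function(rel) {
  list(type = rel$type,
       attributes = rel$attributes[sort(names(rel$attributes))],
       provenance = sort(rel$provenance), evidence = sort(rel$evidence))
}

# id-preserving signature: named by id (exact equality after round trips)
kg_signature <- function(g) {
  cons <- lapply(as.character(kg_concept_ids(g)), function(k)
    concept_signature(g$concepts[[k]]))
  names(cons) <- as.character(kg_concept_ids(g))
  rels <- lapply(as.character(kg_relation_ids(g)), function(k) {
    rel <- g$relations[[k]]
    c(list(from = rel$from, to = rel$to), relation_signature(rel))
  })
  names(rels) <- as.character(kg_relation_ids(g))
  list(concepts = cons, relations = rels)
}

# label-based signature: independent of concept/relation ids, for
# permutation-invariance checks; concepts keyed by their accession set
kg_label_signature <- function(g) {
  key_of <- function(con) paste(sort(vapply(con$accessions, function(a)
    paste0(a$namespace, ":", a$value), character(1))), collapse = "|")
  cons <- lapply(as.character(kg_concept_ids(g)), function(k)
    g$concepts[[k]])
  sigs <- lapply(cons, concept_signature)
  keys <- vapply(cons, key_of, character(1))
  o <- order(keys)
  cmap <- setNames(keys, vapply(cons, function(c) as.character(c$id), character(1)))
  rels <- sort(vapply(as.character(kg_relation_ids(g)), function(k) {
    rel <- g$relations[[k]]
    paste(cmap[[as.character(rel$from)]], rel$type, cmap[[as.character(rel$to)]])
  }, character(1)))
  list(concepts = setNames(sigs[o], keys[o]), relations = rels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
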