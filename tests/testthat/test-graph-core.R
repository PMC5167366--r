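test_that("meta-model validation catches broken references and cycles", {
  m <- metamodel_default()
  expect_s3_class(kg_new(m), "kg")

  bad_parent <- metamodel_default()
  bad_parent$concept_classes <- rbind(
    bad_parent$concept_classes,
    data.frame(id = "X", label = "X", parent = "NoSuchClass"))
  expect_error(kg_new(bad_parent), "unresolved parent")

  cyc <- metamodel_default()
  cyc$concept_classes$parent[cyc$concept_classes$id == "Thing"] <- "Gene"
  # independent cycle detection: follow parents from every node
  parents <- setNames(cyc$concept_classes$parent, cyc$concept_classes$id)
  has_cycle <- any(vapply(names(parents), function(start) {
    seen <- character(0); node <- start
    while (!is.na(node) && node %in% names(parents)) {
      if (node %in% seen) return(TRUE)
      seen <- c(seen, node); node <- parents[[node]]
    }
    FALSE
  }, logical(1)))
  expect_true(has_cycle)
  expect_error(kg_new(cyc), "cyclic")

  dup <- metamodel_default()
  dup$data_sources <- rbind(dup$data_sources, dup$data_sources[1, ])
  expect_error(kg_new(dup), "duplicate")
})

test_that("meta-model YAML serialisation round-trips", {
  m <- metamodel_default()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_metamodel(m, path)
  m2 <- read_metamodel(path)
  expect_equal(m2$concept_classes, m$concept_classes)
  expect_equal(m2$relation_types, m$relation_types)
  expect_equal(m2$attribute_names, m$attribute_names)
})

test_that("concepts sharing an accession merge into one representative", {
  g <- kg_new()
  a <- upsert_concept(g, "Protein",
                      accessions = list(acc("ENSEMBL", "TRAES_2AL_65B19CC73.1")),
                      source = "ENSEMBL")
  b <- upsert_concept(g, "Protein",
                      accessions = list(acc("ENSEMBL", "TRAES_2AL_65B19CC73.1")),
                      preferred_name = "WRKY44", source = "UNIPROT")
  expect_identical(a, b)
  expect_equal(kg_concept_count(g), 1L)
  expect_setequal(kg_concept(g, a)$provenance, c("ENSEMBL", "UNIPROT"))

  # no accessions: nothing to merge on
  c1 <- upsert_concept(g, "Gene", preferred_name = "x")
  c2 <- upsert_concept(g, "Gene", preferred_name = "x")
  expect_false(c1 == c2)

  # same accession on different classes never merges
  g2 <- kg_new()
  p <- upsert_concept(g2, "Protein", accessions = list(acc("TAIR", "AT2G37260")))
  ge <- upsert_concept(g2, "Gene", accessions = list(acc("TAIR", "AT2G37260")))
  expect_false(p == ge)

  # ambiguous accessions never drive merging
  g3 <- kg_new()
  a1 <- upsert_concept(g3, "Gene", accessions = list(acc("UC", "AMB1", ambiguous = TRUE)))
  a2 <- upsert_concept(g3, "Gene", accessions = list(acc("UC", "AMB1", ambiguous = TRUE)))
  expect_false(a1 == a2)

  expect_error(upsert_concept(g, "NoSuchClass"), class = "gsknet_meta_error")
  expect_error(upsert_concept(g, "Gene", attributes = list(Bogus = 1)),
               class = "gsknet_meta_error")
})

test_that("repeated upserts fold attributes like a brute-force fold", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    ups <- lapply(seq_len(n), function(i) {
      attrs <- list()
      if (runif(1) < .8) attrs$TAXID <- sample(c("1", "2", "3"), 1)
      if (runif(1) < .5) attrs$Score <- round(runif(1), 3)
      if (runif(1) < .4) attrs$Title <- sprintf("t%d", i)
      list(attrs = attrs, source = sample(c("TAIR", "UNIPROT", "GO"), 1))
    })
    g <- kg_new()
    for (u in ups)
      upsert_concept(g, "Gene", accessions = list(acc("UC", "SHARED")),
                     attributes = u$attrs, source = u$source)
    expect_equal(kg_concept_count(g), 1L)
    con <- kg_concept(g, kg_concept_ids(g)[1])
    # oracle: plain left-to-right fold with last-writer-wins
    folded <- Reduce(function(acc_attrs, u) modifyList(acc_attrs, u$attrs),
                     ups, init = list())
    expect_equal(con$attributes[sort(names(con$attributes))],
                 folded[sort(names(folded))])
    expect_setequal(con$provenance, unique(vapply(ups, `[[`, character(1), "source")))
  }
})

test_that("upsert order does not change the resulting graph", {
  set.seed(99)
  ups <- list(
    list(class = "Gene", accs = list(acc("UC", "A")), name = "alpha"),
    list(class = "Gene", accs = list(acc("UC", "B"))),
    list(class = "Gene", accs = list(acc("UC", "A"), acc("UC", "B"))),  # bridge
    list(class = "Protein", accs = list(acc("UC", "A"))),
    list(class = "Gene", accs = list(acc("UC", "C")), name = "gamma"),
    list(class = "Gene", accs = list(acc("UC", "C"), acc("UC", "D")))
  )
  build <- function(order) {
    g <- kg_new()
    for (u in ups[order])
      upsert_concept(g, u$class, accessions = u$accs,
                     synonyms = if (!is.null(u$name)) u$name else character(0))
    g
  }
  ref <- kg_label_signature(build(seq_along(ups)))
  for (i in 1:8) {
    sig <- kg_label_signature(build(sample(seq_along(ups))))
    expect_equal(sig$concepts, ref$concepts)
  }
  # after any order, no two same-class concepts share a non-ambiguous accession
  g <- build(sample(seq_along(ups)))
  for (key in ls(g$acc_index)) {
    ids <- g$acc_index[[key]]
    cls <- vapply(ids, function(i) kg_concept(g, i)$class, character(1))
    expect_equal(anyDuplicated(cls), 0L)
  }
})

test_that("relations deduplicate on (from, to, type), symmetric types unordered", {
  g <- kg_new()
  g1 <- upsert_concept(g, "Gene", accessions = list(acc("UC", "G1")))
  p1 <- upsert_concept(g, "Protein", accessions = list(acc("UC", "P1")))
  r1 <- add_relation(g, g1, p1, "encodes", source = "ENSEMBL")
  r2 <- add_relation(g, g1, p1, "encodes", source = "TAIR")
  expect_identical(r1, r2)
  expect_equal(kg_relation_count(g), 1L)
  expect_setequal(kg_relation(g, r1)$provenance, c("ENSEMBL", "TAIR"))

  e1 <- add_relation(g, g1, p1, "equal")   # symmetric
  e2 <- add_relation(g, p1, g1, "equal")
  expect_identical(e1, e2)

  # directed types keep both directions as distinct relations
  d1 <- add_relation(g, g1, p1, "published_in")
  d2 <- add_relation(g, p1, g1, "published_in")
  expect_false(d1 == d2)

  expect_error(add_relation(g, g1, 999L, "encodes"), class = "gsknet_graph_error")
  expect_error(add_relation(g, g1, p1, "nonsense"), class = "gsknet_meta_error")
})

test_that("relation multiset equals a log-replay dedupe oracle", {
  set.seed(7)
  g <- kg_new()
  ids <- vapply(1:12, function(i)
    upsert_concept(g, "Protein", accessions = list(acc("UC", sprintf("P%d", i)))),
    integer(1))
  types <- c("encodes", "equal", "ortholog", "published_in")
  log <- data.frame(from = sample(ids, 100, TRUE), to = sample(ids, 100, TRUE),
                    type = sample(types, 100, TRUE))
  log <- log[log$from != log$to, , drop = FALSE]
  for (i in seq_len(nrow(log)))
    add_relation(g, log$from[i], log$to[i], log$type[i])
  # oracle: canonicalise symmetric pairs and count unique triples
  sym <- c(equal = TRUE, ortholog = TRUE, encodes = FALSE, published_in = FALSE)
  key <- ifelse(sym[log$type],
                paste(pmin(log$from, log$to), pmax(log$from, log$to), log$type),
                paste(log$from, log$to, log$type))
  expect_equal(kg_relation_count(g), length(unique(key)))
})

test_that("metagraph counts every class and triple and conserves totals", {
  g <- kg_new()
  expect_length(kg_metagraph(g)$nodes, 0)
  expect_equal(nrow(kg_metagraph(g)$edges), 0)

  for (i in 1:2) {
    ge <- upsert_concept(g, "Gene", accessions = list(acc("UC", sprintf("g%d", i))))
    pr <- upsert_concept(g, "Protein", accessions = list(acc("UC", sprintf("p%d", i))))
    add_relation(g, ge, pr, "encodes")
  }
  mg <- kg_metagraph(g)
  expect_equal(mg$nodes[["Gene"]], 2L)
  expect_equal(mg$nodes[["Protein"]], 2L)
  expect_equal(mg$edges$count[mg$edges$from_class == "Gene" &
                              mg$edges$type == "encodes" &
                              mg$edges$to_class == "Protein"], 2L)
  expect_equal(sum(mg$nodes), kg_concept_count(g))
  expect_equal(sum(mg$edges$count), kg_relation_count(g))

  set.seed(5)
  for (i in 1:5) {
    gr <- rand_kg(n_concepts = sample(10:40, 1), n_relations = sample(10:60, 1))
    mgr <- kg_metagraph(gr)
    expect_equal(sum(mgr$nodes), kg_concept_count(gr))
    expect_equal(sum(mgr$edges$count), kg_relation_count(gr))
  }
})

test_that("accession and name indexes agree with a full rescan", {
  set.seed(11)
  g <- rand_kg(n_concepts = 40, n_relations = 30)
  for (key in ls(g$acc_index)) {
    parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    rescan <- Filter(function(id) {
      con <- kg_concept(g, id)
      any(vapply(con$accessions, function(a)
        a$namespace == parts[1] && a$value == parts[2], logical(1)))
    }, kg_concept_ids(g))
    expect_setequal(g$acc_index[[key]], rescan)
  }
  for (key in ls(g$name_index)) {
    rescan <- Filter(function(id) {
      con <- kg_concept(g, id)
      any(tolower(gsub("[[:space:]]+", " ", trimws(con$names$name))) == key)
    }, kg_concept_ids(g))
    expect_setequal(g$name_index[[key]], rescan)
  }
})

test_that("kg_union copies without merging; subgraph preserves ids", {
  g1 <- kg_new()
  a <- upsert_concept(g1, "Gene", accessions = list(acc("UC", "X")))
  g2 <- kg_new()
  b <- upsert_concept(g2, "Gene", accessions = list(acc("UC", "X")))
  p <- upsert_concept(g2, "Protein", accessions = list(acc("UC", "Y")))
  add_relation(g2, b, p, "encodes")
  u <- kg_new()
  kg_union(u, g1, g2)
  expect_equal(kg_concept_count(u), 3L)           # no merge on union
  expect_length(kg_find_accession(u, "UC", "X"), 2L)
  expect_equal(kg_relation_count(u), 1L)

  sub <- kg_subgraph(u, kg_find_accession(u, "UC", "X"))
  expect_equal(kg_concept_count(sub), 2L)
  expect_equal(kg_relation_count(sub), 0L)        # protein dropped
})

test_that("attribute overwrites during merge are retained in the audit trail", {
  g <- kg_new()
  upsert_concept(g, "Gene", accessions = list(acc("UC", "A")),
                 attributes = list(Title = "first"))
  upsert_concept(g, "Gene", accessions = list(acc("UC", "A")),
                 attributes = list(Title = "second"), source = "TAIR")
  con <- kg_concept(g, kg_concept_ids(g)[1])
  expect_equal(con$attributes$Title, "second")
  audit <- kg_audit(g)
  expect_length(audit, 1)
  expect_equal(audit[[1]]$overwritten, "first")
})
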