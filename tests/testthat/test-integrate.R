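test_that("accession mapping links same-class concepts sharing identifiers", {
  g <- kg_new()
  p1 <- upsert_concept(g, "Protein", accessions = list(acc("UNIPROT", "P0XXX1")),
                       source = "UNIPROT")
  p2 <- upsert_concept(g, "Protein", accessions = list(acc("UNIPROT", "P0XXX1")),
                       source = "TAIR", merge = FALSE)
  ge <- upsert_concept(g, "Gene", accessions = list(acc("UNIPROT", "P0XXX1")))
  n <- accession_map(g)
  expect_equal(n, 1L)                       # gene/protein class mismatch: no link
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_equal(rel$type, "equal")
  expect_setequal(c(rel$from, rel$to), c(p1, p2))
  expect_equal(accession_map(g), 0L)        # idempotent

  # ambiguous accessions excluded
  g2 <- kg_new()
  upsert_concept(g2, "Gene", accessions = list(acc("UC", "A", ambiguous = TRUE)))
  upsert_concept(g2, "Gene", accessions = list(acc("UC", "A", ambiguous = TRUE)))
  expect_equal(accession_map(g2), 0L)
})

test_that("accession mapping equals the all-pairs oracle on random graphs", {
  set.seed(17)
  for (rep in 1:10) {
    g <- kg_new()
    n <- sample(15:40, 1)
    info <- list()
    for (i in seq_len(n)) {
      cls <- sample(c("Gene", "Protein"), 1)
      vals <- sample(sprintf("V%d", 1:12), sample(1:2, 1))
      amb <- runif(length(vals)) < 0.2
      cid <- upsert_concept(g, cls,
                            accessions = Map(function(v, a) acc("UC", v, a), vals, amb),
                            merge = FALSE)
      info[[as.character(cid)]] <- list(class = cls, vals = vals, amb = amb)
    }
    added <- accession_map(g)
    # oracle: O(n^2) scan over concepts
    ids <- as.integer(names(info))
    expected <- character(0)
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      a <- info[[i]]; b <- info[[j]]
      if (a$class != b$class) next
      shared <- intersect(a$vals[!a$amb], b$vals[!b$amb])
      if (length(shared))
        expected <- c(expected, paste(ids[i], ids[j]))
    }
    got <- vapply(Filter(function(rid) kg_relation(g, rid)$type == "equal",
                         kg_relation_ids(g)), function(rid) {
      rel <- kg_relation(g, rid)
      paste(min(rel$from, rel$to), max(rel$from, rel$to))
    }, character(1))
    expect_setequal(got, expected)
    expect_equal(added, length(expected))
  }
})

test_that("name mapping is case-folded and length-limited", {
  g <- kg_new()
  a <- upsert_concept(g, "Gene", accessions = list(acc("UC", "1")),
                      preferred_name = "TTG2")
  b <- upsert_concept(g, "Gene", accessions = list(acc("UC", "2")),
                      synonyms = "ttg2")
  upsert_concept(g, "Gene", accessions = list(acc("UC", "3")),
                 preferred_name = "ab")
  upsert_concept(g, "Gene", accessions = list(acc("UC", "4")),
                 preferred_name = "AB")
  expect_equal(name_map(g), 1L)             # "ab" below min_len
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_setequal(c(rel$from, rel$to), c(a, b))

  # oracle over random synonym sets
  set.seed(29)
  for (rep in 1:5) {
    g2 <- kg_new()
    pool <- sprintf("NAME%d", 1:6)
    recs <- list()
    for (i in 1:12) {
      nms <- sample(pool, sample(1:3, 1))
      cid <- upsert_concept(g2, "Protein", accessions = list(acc("UC", as.character(i))),
                            synonyms = nms)
      recs[[as.character(cid)]] <- nms
    }
    added <- name_map(g2)
    ids <- as.integer(names(recs))
    expected <- 0L
    for (i in seq_along(ids)) for (j in seq_along(ids))
      if (i < j && length(intersect(tolower(recs[[i]]), tolower(recs[[j]]))))
        expected <- expected + 1L
    expect_equal(added, expected)
  }
})

test_that("co-location links overlapping gene/QTL intervals on the same map", {
  g <- kg_new()
  ge <- make_located(g, "Gene", "5", 150, 200, "bp")
  qt <- make_located(g, "QTL", "5", 100, 300, "bp")
  expect_equal(colocation_map(g), 1L)

  # genetic-map point inside a QTL interval
  g2 <- kg_new()
  ge2 <- make_located(g2, "Gene", "5H", 48.2, 48.2, "cM")
  qt2 <- make_located(g2, "QTL", "5H", 40, 55, "cM")
  expect_equal(colocation_map(g2), 1L)
  rel <- kg_relation(g2, kg_relation_ids(g2)[1])
  expect_equal(rel$type, "colocated")
  expect_equal(rel$from, ge2)               # directed Gene -> QTL

  # unit mismatch never matches
  g3 <- kg_new()
  make_located(g3, "Gene", "5", 150, 200, "bp")
  make_located(g3, "QTL", "5", 100, 300, "cM")
  expect_equal(colocation_map(g3), 0L)

  # taxid mismatch never matches
  g4 <- kg_new()
  make_located(g4, "Gene", "5", 150, 200, "bp", taxid = "1")
  make_located(g4, "QTL", "5", 100, 300, "bp", taxid = "2")
  expect_equal(colocation_map(g4), 0L)
})

test_that("proximity respects interval boundaries and the window", {
  g <- kg_new()
  sn <- make_located(g, "SNP", "1", 500, 500, "bp")
  make_located(g, "Gene", "1", 400, 600, "bp")
  expect_equal(proximity_map(g, window = 0), 1L)

  g2 <- kg_new()
  make_located(g2, "SNP", "1", 399, 399, "bp")
  make_located(g2, "Gene", "1", 400, 600, "bp")
  expect_equal(proximity_map(g2, window = 0), 0L)
  g3 <- kg_new()
  make_located(g3, "SNP", "1", 399, 399, "bp")
  make_located(g3, "Gene", "1", 400, 600, "bp")
  expect_equal(proximity_map(g3, window = 1), 1L)
})

test_that("interval operators equal the brute-force overlap oracle", {
  set.seed(53)
  for (rep in 1:12) {
    g <- kg_new()
    subs <- list(); targs <- list()
    for (i in 1:sample(8:25, 1)) {
      chrom <- sample(c("1", "2"), 1)
      unit <- sample(c("bp", "cM"), 1)
      b <- sample.int(1000, 1); e <- b + sample(0:200, 1)
      id <- make_located(g, "Gene", chrom, b, e, unit)
      subs[[length(subs) + 1L]] <- list(id = id, chrom = chrom, begin = b,
                                        end = e, unit = unit, taxid = "1")
    }
    for (i in 1:sample(5:15, 1)) {
      chrom <- sample(c("1", "2"), 1)
      unit <- sample(c("bp", "cM"), 1)
      b <- sample.int(1000, 1); e <- b + sample(0:400, 1)
      id <- make_located(g, "QTL", chrom, b, e, unit)
      targs[[length(targs) + 1L]] <- list(id = id, chrom = chrom, begin = b,
                                          end = e, unit = unit, taxid = "1")
    }
    n <- colocation_map(g)
    expected <- oracle_overlap_pairs(subs, targs)
    got <- vapply(Filter(function(rid) kg_relation(g, rid)$type == "colocated",
                         kg_relation_ids(g)), function(rid) {
      rel <- kg_relation(g, rid)
      paste(rel$from, rel$to)
    }, character(1))
    expect_setequal(got, expected)
    expect_equal(n, length(expected))

    # proximity with a window, against the same oracle
    w <- sample(0:50, 1)
    n2 <- proximity_map(g, subject_class = "Gene", target_class = "QTL",
                        window = w, type = "in_proximity")
    expected2 <- oracle_overlap_pairs(subs, targs, window = w)
    got2 <- vapply(Filter(function(rid) kg_relation(g, rid)$type == "in_proximity",
                          kg_relation_ids(g)), function(rid) {
      rel <- kg_relation(g, rid)
      paste(rel$from, rel$to)
    }, character(1))
    expect_setequal(got2, expected2)
    expect_equal(n2, length(expected2))
  }
})

test_that("external2go adds cross references only where both ends exist", {
  g <- kg_new()
  dom <- upsert_concept(g, "ProtDomain", accessions = list(acc("INTERPRO", "IPR003657")))
  go <- upsert_concept(g, "MolFunc", accessions = list(acc("GO", "GO:0003700")))
  map <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!comment",
    "InterPro:IPR003657 WRKY DNA-binding domain > GO:tf activity ; GO:0003700",
    "InterPro:IPR003657 WRKY DNA-binding domain > GO:absent ; GO:0099999",
    "InterPro:IPR999999 missing domain > GO:tf activity ; GO:0003700",
    "this line is malformed"), map)
  expect_warning(res <- external2go_map(g, map), "malformed")
  expect_equal(res$added, 1L)
  expect_equal(res$unmatched, 2L)
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_equal(rel$type, "cross_reference")
  expect_setequal(c(rel$from, rel$to), c(dom, go))
})

test_that("collapsing a chain unifies provenance and is idempotent", {
  g <- kg_new()
  a <- upsert_concept(g, "Protein", accessions = list(acc("UC", "A")), source = "TAIR")
  b <- upsert_concept(g, "Protein", accessions = list(acc("UC", "B")), source = "UNIPROT")
  c3 <- upsert_concept(g, "Protein", accessions = list(acc("UC", "C")), source = "ENSEMBL")
  pub <- upsert_concept(g, "Publication", accessions = list(acc("PMID", "9")))
  add_relation(g, c3, pub, "published_in")
  add_relation(g, a, b, "equal"); add_relation(g, b, c3, "equal")
  rep1 <- collapse_equal(g)
  expect_equal(rep1$groups, 1L)
  expect_equal(kg_concept_count(g), 2L)
  survivor <- kg_concept(g, a)               # lowest id is the representative
  expect_setequal(survivor$provenance, c("TAIR", "UNIPROT", "ENSEMBL"))
  expect_setequal(vapply(survivor$accessions, `[[`, character(1), "value"),
                  c("A", "B", "C"))
  # the published_in relation was rewired to the representative
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_equal(rel$from, a)
  expect_equal(rel$type, "published_in")
  # idempotence
  sig <- kg_signature(g)
  rep2 <- collapse_equal(g)
  expect_equal(rep2$groups, 0L)
  expect_equal(kg_signature(g), sig)
})

test_that("cross-class equal components are rejected, not merged", {
  g <- kg_new()
  a <- upsert_concept(g, "Gene", accessions = list(acc("UC", "A")))
  b <- upsert_concept(g, "Protein", accessions = list(acc("UC", "B")))
  add_relation(g, a, b, "equal")
  rep <- collapse_equal(g)
  expect_equal(rep$groups, 0L)
  expect_length(rep$rejected, 1)
  expect_setequal(rep$rejected[[1]], c(a, b))
  expect_equal(kg_concept_count(g), 2L)
})

test_that("collapse matches the union-find oracle and conserves content", {
  set.seed(61)
  for (rep in 1:15) {
    g <- kg_new()
    n <- sample(20:80, 1)
    classes <- character(0)
    for (i in seq_len(n)) {
      cls <- sample(c("Gene", "Protein", "Trait"), 1)
      classes[as.character(i)] <- cls
      upsert_concept(g, cls, accessions = list(acc("UC", sprintf("C%03d", i))),
                     source = sprintf("SRC%03d", i))   # unique provenance
    }
    ids <- kg_concept_ids(g)
    edges <- data.frame(from = integer(0), to = integer(0))
    for (k in seq_len(sample(5:40, 1))) {
      pair <- sample(ids, 2)
      add_relation(g, pair[1], pair[2], "equal")
      edges <- rbind(edges, data.frame(from = pair[1], to = pair[2]))
    }
    acc_before <- sort(unlist(lapply(ids, function(i)
      vapply(kg_concept(g, i)$accessions, `[[`, character(1), "value"))))
    prov_before <- sort(unlist(lapply(ids, function(i) kg_concept(g, i)$provenance)))

    collapse_equal(g)

    expected <- oracle_collapse_partition(ids, classes, edges)
    # every expected group must exist as exactly one concept holding the
    # union of the group's accessions
    after_ids <- kg_concept_ids(g)
    expect_equal(length(after_ids), length(expected))
    got_groups <- lapply(after_ids, function(i)
      sort(as.integer(sub("C", "", vapply(kg_concept(g, i)$accessions,
                                          `[[`, character(1), "value")))))
    got_groups <- got_groups[order(vapply(got_groups, min, numeric(1)))]
    expected_sorted <- expected[order(vapply(expected, min, numeric(1)))]
    expect_equal(got_groups, lapply(expected_sorted, as.integer))

    # conservation of accessions and provenance multisets
    prov_after <- sort(unlist(lapply(after_ids, function(i) kg_concept(g, i)$provenance)))
    acc_after <- sort(unlist(lapply(after_ids, function(i)
      vapply(kg_concept(g, i)$accessions, `[[`, character(1), "value"))))
    expect_equal(acc_after, acc_before)
    expect_equal(prov_after, prov_before)
  }
})
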