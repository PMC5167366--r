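write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("FASTA-GFF3 parsing builds the Gene-Protein network", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "1H\ttest\tgene\t100\t500\t.\t+\t.\tID=g1;Name=GENE1",
    "1H\ttest\tmRNA\t100\t500\t.\t+\t.\tID=g1.1;Parent=g1",
    "1H\ttest\tCDS\t100\t500\t.\t+\t0\tID=c1;Parent=g1.1"), ".gff3")
  fa <- write_tmp(c(">g1.1", "MKWRKY"), ".fa")
  g <- parse_fasta_gff3(gff, fa, taxid = "4565")
  mg <- kg_metagraph(g)
  expect_equal(mg$nodes[["Gene"]], 1L)
  expect_equal(mg$nodes[["Protein"]], 1L)
  expect_equal(sum(mg$edges$count[mg$edges$type == "encodes"]), 1L)
  gid <- kg_find_accession(g, "ENSEMBL", "g1")
  expect_equal(kg_attr(g, gid, "Chromosome"), "1H")
  expect_equal(kg_attr(g, gid, "BEGIN"), 100L)
  expect_equal(kg_attr(g, gid, "END"), 500L)
  expect_equal(kg_attr(g, gid, "TAXID"), "4565")
  loc <- kg_attr(g, gid, "Location")
  expect_equal(loc$unit, "bp")
  pid <- kg_find_accession(g, "ENSEMBL", "g1.1")
  expect_equal(kg_attr(g, pid, "AA"), "MKWRKY")
})

test_that("a gene with two products yields two encodes relations", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "2B\ttest\tgene\t1\t900\t.\t-\t.\tID=g1",
    "2B\ttest\tmRNA\t1\t900\t.\t-\t.\tID=g1.1;Parent=g1",
    "2B\ttest\tmRNA\t1\t900\t.\t-\t.\tID=g1.2;Parent=g1"), ".gff3")
  fa <- write_tmp(c(">g1.1", "MKAA", ">g1.2", "MKCC", ">orphan.1", "MKDD"), ".fa")
  expect_warning(g <- parse_fasta_gff3(gff, fa, taxid = "4565"),
                 "no GFF3 counterpart")
  mg <- kg_metagraph(g)
  expect_equal(mg$nodes[["Gene"]], 1L)
  expect_equal(mg$nodes[["Protein"]], 3L)   # orphan kept
  expect_equal(sum(mg$edges$count[mg$edges$type == "encodes"]), 2L)
})

test_that("malformed GFF3 lines are reported with their line number", {
  gff <- write_tmp(c("##gff-version 3",
                     "1H\ttest\tgene\t100\t500\t.\t+\t.\tID=g1",
                     "1H\tbroken line without tabs"), ".gff3")
  fa <- write_tmp(c(">g1.1", "MK"), ".fa")
  expect_error(parse_fasta_gff3(gff, fa, "1"), "line 3")
})

test_that("OBO parsing creates term concepts with hierarchy relations", {
  obo <- write_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: TO:0000001", "name: seed width",
    'synonym: "grain width" EXACT []', "is_a: TO:0000002 ! seed size", "",
    "[Term]", "id: TO:0000002", "name: seed size", "",
    "[Term]", "id: TO:0000009", "name: gone", "is_obsolete: true"), ".obo")
  g <- parse_obo(obo, class = "TO")
  expect_equal(kg_concept_count(g), 2L)      # obsolete excluded
  expect_equal(kg_relation_count(g), 1L)
  tid <- kg_find_accession(g, "TO", "TO:0000001")
  expect_equal(kg_preferred_name(g, tid), "seed width")
  expect_true("grain width" %in% kg_concept(g, tid)$names$name)
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_equal(rel$type, "is_a")

  # GO namespaces select the concept class
  obo2 <- write_tmp(c(
    "[Term]", "id: GO:0003700", "name: tf activity",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0048316", "name: seed development",
    "namespace: biological_process",
    "relationship: part_of GO:9999999 ! dangling"), ".obo")
  expect_warning(g2 <- parse_obo(obo2), "dangling")
  cls <- sort(vapply(kg_concept_ids(g2), function(i) kg_concept(g2, i)$class,
                     character(1)))
  expect_equal(unname(cls), c("BioProc", "MolFunc"))
  expect_equal(kg_relation_count(g2), 0L)
})

test_that("GAF rows map aspects to relation types and honour NOT", {
  gaf_line <- function(gene, go, aspect, qual = "") {
    paste(c("ENSEMBL", gene, toupper(gene), qual, go, "GO_REF:1", "IDA", "",
            aspect, "", "", "gene", "taxon:4565", "20160601", "t", "", ""),
          collapse = "\t")
  }
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     gaf_line("g1", "GO:0000001", "P"),
                     gaf_line("g1", "GO:0000002", "F"),
                     gaf_line("g2", "GO:0000003", "C"),
                     gaf_line("g3", "GO:0000001", "P", qual = "NOT")), ".gaf")
  g <- parse_gaf(gaf)
  mg <- kg_metagraph(g)
  per_type <- setNames(mg$edges$count, mg$edges$type)
  expect_equal(per_type[["participates_in"]], 1L)
  expect_equal(per_type[["has_function"]], 1L)
  expect_equal(per_type[["located_in"]], 1L)
  expect_equal(mg$nodes[["Gene"]], 2L)       # NOT row contributes nothing
  rel <- kg_relation(g, kg_relation_ids(g)[1])
  expect_true("IDA" %in% rel$evidence)

  bad <- write_tmp(c(gaf_line("g1", "GO:1", "Z")), ".gaf")
  expect_error(parse_gaf(bad), "aspect")
  badtype <- write_tmp(sub("\tgene\t", "\tplasmid\t",
                           gaf_line("g1", "GO:1", "P")), ".gaf")
  expect_error(parse_gaf(badtype), "object type")
})

test_that("tabular import follows the column bindings and merges subjects", {
  tsv <- write_tmp(c("gene\tsnp\tchrom\tpos",
                     "g1\ts1\t1H\t100",
                     "g1\ts2\t1H\t200",
                     "g1\ts3\t2B\t300",
                     "\ts4\t2B\t400"), ".tsv")
  spec <- table_spec(
    subject = list(class = "Gene", accession_col = "gene", namespace = "ENSEMBL"),
    object = list(class = "SNP", accession_col = "snp", namespace = "ENSEMBL",
                  location = list(attribute = "Location", chromosome_col = "chrom",
                                  begin_col = "pos", unit = "bp", taxid = "4565")),
    relation = "has_variance", source = "ENSEMBL", taxid = "4565")
  expect_warning(g <- parse_tabular(tsv, spec), "empty accession")
  mg <- kg_metagraph(g)
  expect_equal(mg$nodes[["Gene"]], 1L)   # merged on repeated accession
  expect_equal(mg$nodes[["SNP"]], 3L)
  expect_equal(sum(mg$edges$count[mg$edges$type == "has_variance"]), 3L)
  s1 <- kg_find_accession(g, "ENSEMBL", "s1")
  expect_equal(kg_attr(g, s1, "Location")$begin, 100)

  # adding genetic-map coordinates to existing gene accessions
  pop <- write_tmp(c("gene\tchrom\tcM", "g1\t1H\t48.2"), ".tsv")
  spec2 <- table_spec(subject = list(
    class = "Gene", accession_col = "gene", namespace = "ENSEMBL",
    location = list(attribute = "GenMapLocation", chromosome_col = "chrom",
                    begin_col = "cM", unit = "cM", taxid = "4565")))
  g2 <- parse_tabular(pop, spec2)
  gid <- kg_find_accession(g2, "ENSEMBL", "g1")
  expect_equal(kg_attr(g2, gid, "GenMapLocation")$begin, 48.2)
  expect_equal(kg_attr(g2, gid, "GenMapLocation")$unit, "cM")

  expect_error(parse_tabular(tsv, table_spec(subject = list(
    class = "Gene", accession_col = "nope", namespace = "UC"))),
    class = "gsknet_spec_error")
  expect_error(table_spec(subject = list(class = "Gene")),
               class = "gsknet_spec_error")
})

test_that("publication records parse from XML and TSV with PMID merging", {
  xml <- write_tmp(c(
    '<?xml version="1.0"?>', "<PubmedArticleSet>",
    " <PubmedArticle><PMID>22251317</PMID>",
    "  <ArticleTitle>T1</ArticleTitle>",
    "  <AbstractText>Seed coat development.</AbstractText></PubmedArticle>",
    " <PubmedArticle><PMID>22251317</PMID>",
    "  <ArticleTitle>T1 dup</ArticleTitle>",
    "  <AbstractText>Duplicate record.</AbstractText></PubmedArticle>",
    " <PubmedArticle><PMID>15598800</PMID>",
    "  <ArticleTitle>T2</ArticleTitle><AbstractText></AbstractText></PubmedArticle>",
    "</PubmedArticleSet>"), ".xml")
  g <- parse_publications(xml)
  expect_equal(kg_concept_count(g), 2L)     # duplicate PMID merged
  pid <- kg_find_accession(g, "PMID", "22251317")
  expect_length(pid, 1)
  p2 <- kg_find_accession(g, "PMID", "15598800")
  expect_null(kg_attr(g, p2, "Abstract"))   # empty abstract omitted

  tsv <- write_tmp(c("pmid\ttitle\tabstract", "1\tA\ttext here"), ".tsv")
  g2 <- parse_publications(tsv)
  expect_equal(kg_concept_count(g2), 1L)
  expect_equal(kg_attr(g2, kg_find_accession(g2, "PMID", "1"), "Abstract"),
               "text here")
})

test_that("reviewed-protein table expands to GO, literature and phenotypes", {
  tsv <- write_tmp(c(
    "accession\tname\ttaxid\tsequence\tgo_terms\tpmids\tphenotype",
    "P1\tTTG2\t3702\tMKWRKY\tF:GO:0003700;P:GO:0048316\t22251317;15598800\tsmaller seeds",
    "P2\tOTHER\t3702\tMKAA\tX:GO:bad\t\t"), ".tsv")
  expect_warning(g <- parse_uniprot_min(tsv), "malformed GO")
  mg <- kg_metagraph(g)
  expect_equal(mg$nodes[["Protein"]], 2L)
  expect_equal(mg$nodes[["Phenotype"]], 1L)
  per_type <- tapply(mg$edges$count, mg$edges$type, sum)
  expect_equal(per_type[["published_in"]], 2L)
  expect_equal(per_type[["has_observed_phenotype"]], 1L)
  expect_equal(per_type[["has_function"]], 1L)
  expect_equal(per_type[["participates_in"]], 1L)
  p1 <- kg_find_accession(g, "UNIPROT", "P1")
  phen <- kg_find_name(g, "smaller seeds")
  expect_length(phen, 1)
})
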