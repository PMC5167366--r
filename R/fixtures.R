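# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# 30-residue block shared between the seed gene's protein and its ortholog
# so sequence-based mapping recovers the planted link as well
PLANTED_BLOCK <- "WRKYGQKQVKGSEYPRSYYKCTHPNCPVKK"

#' Generate a synthetic crop + reference input bundle
#'
#' Writes a miniature, fully deterministic set of input files emulating a
#' crop knowledge-network build -- gene models (GFF3 + protein FASTA), a
#' mini GO and a mini Trait Ontology (OBO), GO annotations (GAF), QTL, SNP,
#' POPSEQ, ortholog and protein-domain tables (TSV), a reviewed-protein
#' table, an external2go mapping file and Medline-like abstracts -- plus a
#' ready-to-run `workflow.yaml` and a ground-truth manifest `truth.json`
#' holding every expected tally.
#'
#' The bundle embeds one complete gene-to-trait evidence chain: a
#' "seed width" trait controlled by a QTL on chromosome 5H that co-locates
#' with the seed gene (genetic-map coordinates), whose protein carries a
#' WRKY DNA-binding domain cross-referenced to a GO transcription-factor
#' term, and is orthologous to a reference protein with a "smaller seeds"
#' phenotype and two supporting publications. One abstract mentions the
#' seed gene and the trait term in the same sentence (text-mining
#' positive); a second mentions them in different sentences (negative
#' control). QTL and POPSEQ coordinates are genetic (cM) while SNPs are
#' physical (bp), exercising the unit-matching rule of co-location.
#'
#' @param seed integer seed; the same seed reproduces the bundle
#'   byte-for-byte.
#' @param n_genes number of crop genes (>= 10).
#' @param n_qtl number of QTLs (>= 2; the first two form the planted chain).
#' @param n_snp number of SNPs (>= 1).
#' @param n_pubs number of publications (>= 4; the first two are the
#'   planted positive/negative abstracts).
#' @param out_dir output directory (created if needed).
#' @return the manifest (also written as `truth.json`), invisibly a list.
#' @export
make_crop_fixture <- function(seed = 7, n_genes = 12, n_qtl = 4, n_snp = 20,
                              n_pubs = 6, out_dir) {
  if (n_genes < 10) spec_error("fixture needs n_genes >= 10 (got %d)", n_genes)
  if (n_qtl < 2) spec_error("fixture needs n_qtl >= 2")
  if (n_snp < 1) spec_error("fixture needs n_snp >= 1")
  if (n_pubs < 4) spec_error("fixture needs n_pubs >= 4")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  crop_tax <- "112509"   # barley
  ref_tax <- "3702"      # Arabidopsis

  with_seed(seed, {
    chroms <- paste0(1:7, "H")
    gene_id <- sprintf("CROPG%04d", seq_len(n_genes))
    gene_name <- c("SDW1", sprintf("BGN%03d", seq_len(n_genes)[-1]))
    gene_chrom <- ifelse(seq_len(n_genes) == 1, "5H",
                         chroms[(seq_len(n_genes) %% 7) + 1])
    gene_begin <- 10000L + (seq_len(n_genes) - 1L) * 5000L +
      sample(0:1000, n_genes, replace = TRUE)
    gene_end <- gene_begin + sample(1200:3000, n_genes, replace = TRUE)
    gene_cm <- round(runif(n_genes, 5, 140), 1)
    gene_cm[1] <- 48.2   # inside both planted QTL intervals

    # transcripts: one per gene, gene 2 gets a second product
    tx_gene <- c(seq_len(n_genes), 2L)
    tx_id <- sprintf("%s.%d", gene_id[tx_gene],
                     stats::ave(tx_gene, tx_gene, FUN = seq_along))
    n_tx <- length(tx_id)

    rand_seq <- function(len) paste(sample(AA_ALPHABET, len, replace = TRUE),
                                    collapse = "")
    tx_seq <- vapply(sample(60:90, n_tx, replace = TRUE), rand_seq, character(1))
    # plant the shared block into the seed protein
    tx_seq[1] <- paste0(substr(tx_seq[1], 1, 20), PLANTED_BLOCK,
                        substr(tx_seq[1], 21, nchar(tx_seq[1])))

    ## --- genome.gff3 + proteins.fasta -------------------------------------
    gff <- c("##gff-version 3")
    for (i in seq_len(n_genes))
      gff <- c(gff, sprintf("%s\tgsknet\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                            gene_chrom[i], gene_begin[i], gene_end[i],
                            gene_id[i], gene_name[i]))
    for (j in seq_len(n_tx)) {
      gi <- tx_gene[j]
      gff <- c(gff,
               sprintf("%s\tgsknet\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                       gene_chrom[gi], gene_begin[gi], gene_end[gi],
                       tx_id[j], gene_id[gi]),
               sprintf("%s\tgsknet\tCDS\t%d\t%d\t.\t+\t0\tID=cds.%s;Parent=%s",
                       gene_chrom[gi], gene_begin[gi], gene_end[gi],
                       tx_id[j], tx_id[j]))
    }
    write_lines_lf(gff, file.path(out_dir, "genome.gff3"))

    fasta <- unlist(lapply(seq_len(n_tx), function(j)
      c(paste0(">", tx_id[j]),
        substring(tx_seq[j], seq(1, nchar(tx_seq[j]), 60),
                  pmin(seq(1, nchar(tx_seq[j]), 60) + 59, nchar(tx_seq[j]))))))
    write_lines_lf(fasta, file.path(out_dir, "proteins.fasta"))

    ## --- mini ontologies ---------------------------------------------------
    go_terms <- list(
      list(id = "GO:0003700", name = "DNA-binding transcription factor activity",
           ns = "molecular_function", is_a = "GO:0003677"),
      list(id = "GO:0003677", name = "DNA binding", ns = "molecular_function"),
      list(id = "GO:0009555", name = "pollen development",
           ns = "biological_process", part_of = "GO:0048316"),
      list(id = "GO:0010214", name = "seed coat development",
           ns = "biological_process", is_a = "GO:0048316"),
      list(id = "GO:0048316", name = "seed development", ns = "biological_process"),
      list(id = "GO:2000014", name = "regulation of seed size",
           ns = "biological_process", regulates = "GO:0048316"),
      list(id = "GO:0005634", name = "nucleus", ns = "cellular_component"),
      list(id = "GO:0005737", name = "cytoplasm", ns = "cellular_component"),
      list(id = "GO:0000001", name = "obsolete placeholder",
           ns = "biological_process", obsolete = TRUE)
    )
    write_lines_lf(obo_lines(go_terms, "go"), file.path(out_dir, "mini-go.obo"))

    to_terms <- list(
      list(id = "TO:0000001", name = "seed width", is_a = "TO:0000005"),
      list(id = "TO:0000002", name = "leaf water potential"),
      list(id = "TO:0000003", name = "plant height"),
      list(id = "TO:0000004", name = "grain yield"),
      list(id = "TO:0000005", name = "seed size"),
      list(id = "TO:0000006", name = "disease resistance")
    )
    write_lines_lf(obo_lines(to_terms, "plant_trait_ontology"),
                   file.path(out_dir, "mini-to.obo"))

    go_ns <- vapply(go_terms, function(t) t$ns, character(1))
    go_live <- !vapply(go_terms, function(t) isTRUE(t$obsolete), logical(1))
    onto_rel_counts <- c(
      is_a = sum(vapply(go_terms[go_live], function(t) !is.null(t$is_a), logical(1))) +
             sum(vapply(to_terms, function(t) !is.null(t$is_a), logical(1))),
      part_of = sum(vapply(go_terms[go_live], function(t) !is.null(t$part_of), logical(1))),
      regulates = sum(vapply(go_terms[go_live], function(t) !is.null(t$regulates), logical(1))))

    ## --- annotations.gaf ---------------------------------------------------
    gaf_rows <- list(
      list(gene = 1, go = "GO:0003700", aspect = "F"),
      list(gene = 1, go = "GO:0010214", aspect = "P"),
      list(gene = 2, go = "GO:0009555", aspect = "P"),
      list(gene = 3, go = "GO:0048316", aspect = "P"),
      list(gene = 4, go = "GO:0003677", aspect = "F"),
      list(gene = 5, go = "GO:0005634", aspect = "C"),
      list(gene = 6, go = "GO:0005737", aspect = "C"),
      list(gene = 7, go = "GO:2000014", aspect = "P"),
      list(gene = 8, go = "GO:0009555", aspect = "P", qualifier = "NOT")
    )
    gaf <- c("!gaf-version: 2.1")
    for (r in gaf_rows)
      gaf <- c(gaf, paste(c("ENSEMBL", gene_id[r$gene], gene_name[r$gene],
                            r$qualifier %||% "", r$go, "GO_REF:0000002", "IEA",
                            "", r$aspect, "", "", "gene",
                            paste0("taxon:", crop_tax), "20160601", "gsknet",
                            "", ""), collapse = "\t"))
    write_lines_lf(gaf, file.path(out_dir, "annotations.gaf"))
    gaf_aspects <- table(vapply(Filter(function(r) is.null(r$qualifier), gaf_rows),
                                function(r) r$aspect, character(1)))

    ## --- genetics tables ---------------------------------------------------
    trait_pool <- data.frame(
      id = sprintf("TRAIT%03d", 1:5),
      name = c("seed width", "leaf water potential", "plant height",
               "grain yield", "disease resistance"), stringsAsFactors = FALSE)
    qtl_id <- c("AQDE021", "AQGZ019",
                if (n_qtl > 2) sprintf("QTL%03d", seq_len(n_qtl - 2)))
    qtl_trait <- c(1L, 2L, if (n_qtl > 2) ((seq_len(n_qtl - 2) - 1L) %% 3L) + 3L)
    qtl_chrom <- c("5H", "5H",
                   if (n_qtl > 2) sample(chroms, n_qtl - 2, replace = TRUE))
    qtl_begin <- c(40, 45, if (n_qtl > 2) round(runif(n_qtl - 2, 0, 120), 1))
    qtl_end <- c(55, 60, if (n_qtl > 2) qtl_begin[-(1:2)] + round(runif(n_qtl - 2, 5, 25), 1))
    write_lines_lf(c("qtl_id\ttrait_id\ttrait_name\tchrom\tbegin_cM\tend_cM",
                     sprintf("%s\t%s\t%s\t%s\t%s\t%s", qtl_id,
                             trait_pool$id[qtl_trait], trait_pool$name[qtl_trait],
                             qtl_chrom, fmt_num(qtl_begin), fmt_num(qtl_end))),
                   file.path(out_dir, "qtl.tsv"))

    write_lines_lf(c("gene_id\tchrom\tcM",
                     sprintf("%s\t%s\t%s", gene_id, gene_chrom, fmt_num(gene_cm))),
                   file.path(out_dir, "popseq.tsv"))

    snp_gene <- ((seq_len(n_snp) - 1L) %% n_genes) + 1L
    snp_pos <- pmax(1L, gene_begin[snp_gene] +
                      sample(-2000:4000, n_snp, replace = TRUE))
    snp_id <- sprintf("SNP%05d", seq_len(n_snp))
    write_lines_lf(c("gene_id\tsnp_id\tchrom\tpos",
                     sprintf("%s\t%s\t%s\t%d", gene_id[snp_gene], snp_id,
                             gene_chrom[snp_gene], snp_pos)),
                   file.path(out_dir, "snp.tsv"))

    # ground truth for the interval operators, by direct scan
    colocated <- 0L
    for (i in seq_len(n_genes)) for (q in seq_len(n_qtl))
      if (gene_chrom[i] == qtl_chrom[q] &&
          gene_cm[i] >= qtl_begin[q] && gene_cm[i] <= qtl_end[q])
        colocated <- colocated + 1L
    in_prox <- 0L
    for (s in seq_len(n_snp)) for (i in seq_len(n_genes))
      if (gene_chrom[i] == as.character(gene_chrom[snp_gene[s]]) &&
          snp_pos[s] >= gene_begin[i] && snp_pos[s] <= gene_end[i])
        in_prox <- in_prox + 1L

    ## --- homology, domains, reference proteins ----------------------------
    ref_acc <- sprintf("REFP%04d", 1:4)
    ref_name <- c("TTG2", "KIN7", "RNG1", "DBP2")
    ref_seq <- vapply(sample(60:90, 4, replace = TRUE), rand_seq, character(1))
    ref_seq[1] <- paste0(substr(ref_seq[1], 1, 15), PLANTED_BLOCK,
                         substr(ref_seq[1], 16, nchar(ref_seq[1])))
    orth <- data.frame(crop = tx_id[1:4], ref = ref_acc, stringsAsFactors = FALSE)
    write_lines_lf(c("crop_protein\tref_protein",
                     sprintf("%s\t%s", orth$crop, orth$ref)),
                   file.path(out_dir, "orthologs.tsv"))

    dom <- data.frame(
      protein = c(tx_id[1], tx_id[2], tx_id[3], tx_id[5]),
      domain = c("IPR003657", "IPR011009", "IPR013083", "IPR003657"),
      name = c("WRKY DNA-binding domain", "Protein kinase-like domain",
               "Zinc finger RING/FYVE/PHD-type", "WRKY DNA-binding domain"),
      stringsAsFactors = FALSE)
    write_lines_lf(c("protein_id\tdomain_acc\tdomain_name",
                     sprintf("%s\t%s\t%s", dom$protein, dom$domain, dom$name)),
                   file.path(out_dir, "domains.tsv"))

    write_lines_lf(c(
      "!external2go mapping (synthetic)",
      "InterPro:IPR003657 WRKY DNA-binding domain > GO:DNA-binding transcription factor activity ; GO:0003700",
      "InterPro:IPR011009 Protein kinase-like domain > GO:protein kinase activity ; GO:0099999",
      "InterPro:IPR999999 Unknown domain > GO:nucleus ; GO:0005634"),
      file.path(out_dir, "external2go.txt"))

    pmid_planted <- c("22251317", "15598800")
    pmid_filler <- sprintf("%d", 30000000 + seq_len(n_pubs - 2))
    pmids <- c(pmid_planted, pmid_filler)
    up <- data.frame(
      accession = ref_acc, name = ref_name, taxid = ref_tax, sequence = ref_seq,
      go_terms = c("F:GO:0003700;P:GO:0010214", "P:GO:0009555",
                   "C:GO:0005634", "F:GO:0003677"),
      pmids = c(paste(pmid_planted, collapse = ";"), pmid_filler[1],
                pmid_filler[2], ""),
      phenotype = c("smaller seeds", "", "reduced trichome number", ""),
      stringsAsFactors = FALSE)
    write_lines_lf(c("accession\tname\ttaxid\tsequence\tgo_terms\tpmids\tphenotype",
                     sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s", up$accession, up$name,
                             up$taxid, up$sequence, up$go_terms, up$pmids,
                             up$phenotype)),
                   file.path(out_dir, "uniprot_min.tsv"))

    ## --- abstracts ---------------------------------------------------------
    titles <- c(
      "A WRKY transcription factor underlies grain morphology variation.",
      "Genetic mapping of kernel traits in a doubled haploid population.",
      sprintf("Synthetic survey article %d on cereal genomics.",
              seq_len(n_pubs - 2)))
    abstracts <- c(
      "SDW1 regulates seed width in barley. Mutant lines develop narrower grains under field conditions.",
      "SDW1 was mapped in a doubled haploid population. Differences in seed width were recorded across environments.",
      rep(c("Agronomic performance was evaluated across sites. Marker density improved genomic predictions.",
            "Transcript abundance varied between tissues. No trait associations were tested."),
          length.out = n_pubs - 2))
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>', "<PubmedArticleSet>")
    for (p in seq_len(n_pubs))
      xml <- c(xml, " <PubmedArticle>",
               paste0("  <PMID>", pmids[p], "</PMID>"),
               paste0("  <ArticleTitle>", xesc(titles[p]), "</ArticleTitle>"),
               paste0("  <AbstractText>", xesc(abstracts[p]), "</AbstractText>"),
               " </PubmedArticle>")
    xml <- c(xml, "</PubmedArticleSet>")
    write_lines_lf(xml, file.path(out_dir, "abstracts.xml"))

    ## --- workflow ----------------------------------------------------------
    write_fixture_workflow(file.path(out_dir, "workflow.yaml"), seed, crop_tax)

    ## --- truth manifest ----------------------------------------------------
    manifest <- list(
      seed = seed,
      params = list(n_genes = n_genes, n_qtl = n_qtl, n_snp = n_snp,
                    n_pubs = n_pubs, n_transcripts = n_tx,
                    crop_taxid = crop_tax, ref_taxid = ref_tax),
      files = list(
        `genome.gff3` = list(genes = n_genes, mrnas = n_tx, cds = n_tx),
        `proteins.fasta` = n_tx,
        `mini-go.obo` = list(terms = sum(go_live), obsolete = sum(!go_live)),
        `mini-to.obo` = list(terms = length(to_terms)),
        `annotations.gaf` = list(rows = length(gaf_rows), not_rows = 1L),
        `qtl.tsv` = n_qtl, `snp.tsv` = n_snp, `popseq.tsv` = n_genes,
        `orthologs.tsv` = nrow(orth), `domains.tsv` = nrow(dom),
        `external2go.txt` = 3L, `uniprot_min.tsv` = nrow(up),
        `abstracts.xml` = n_pubs),
      concept_classes = list(
        Gene = n_genes, Protein = n_tx + length(ref_acc), SNP = n_snp,
        QTL = n_qtl, Trait = length(unique(qtl_trait)),
        TO = length(to_terms),
        BioProc = sum(go_ns == "biological_process" & go_live),
        MolFunc = sum(go_ns == "molecular_function" & go_live),
        CelComp = sum(go_ns == "cellular_component" & go_live),
        ProtDomain = length(unique(dom$domain)),
        Publication = n_pubs, Phenotype = sum(nzchar(up$phenotype))),
      relation_types = list(
        encodes = n_tx,
        is_a = unname(onto_rel_counts[["is_a"]]),
        part_of = unname(onto_rel_counts[["part_of"]]),
        regulates = unname(onto_rel_counts[["regulates"]]),
        participates_in = unname(gaf_aspects[["P"]]) +
          sum(grepl("P:GO", up$go_terms, fixed = TRUE)),
        has_function = unname(gaf_aspects[["F"]]) +
          sum(grepl("F:GO", up$go_terms, fixed = TRUE)),
        located_in = unname(gaf_aspects[["C"]]) +
          sum(grepl("C:GO", up$go_terms, fixed = TRUE)),
        control = n_qtl, has_variance = n_snp,
        ortholog = nrow(orth), has_domain = nrow(dom),
        published_in = sum(lengths(strsplit(up$pmids[nzchar(up$pmids)], ";"))),
        has_observed_phenotype = sum(nzchar(up$phenotype)),
        cross_reference = 1L,
        colocated = colocated, in_proximity = in_prox,
        cooccurs_with = 1L),
      gaf_aspects = list(P = unname(gaf_aspects[["P"]]),
                         F = unname(gaf_aspects[["F"]]),
                         C = unname(gaf_aspects[["C"]])),
      external2go = list(matched = 1L, unmatched = 2L),
      textmine = list(relations = 1L,
                      positive = list(gene = gene_name[1], term = "seed width",
                                      pmid = pmid_planted[1]),
                      negative_pmid = pmid_planted[2]),
      chain = list(gene = gene_id[1], gene_name = gene_name[1],
                   protein = tx_id[1], qtls = qtl_id[1:2],
                   trait = trait_pool$id[1], trait_name = trait_pool$name[1],
                   domain = "IPR003657", go = "GO:0003700",
                   ortholog = ref_acc[1], phenotype = "smaller seeds",
                   pmids = pmid_planted, to_term = "TO:0000001"),
      planted_similarity = c(tx_id[1], ref_acc[1]))
    jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  })
}

obo_lines <- function(terms, ontology) {
  out <- c("format-version: 1.2", paste0("ontology: ", ontology))
  for (t in terms) {
    out <- c(out, "", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.null(t$ns)) out <- c(out, paste0("namespace: ", t$ns))
    if (!is.null(t$synonyms))
      out <- c(out, sprintf('synonym: "%s" EXACT []', t$synonyms))
    if (isTRUE(t$obsolete)) out <- c(out, "is_obsolete: true")
    if (!is.null(t$is_a)) out <- c(out, paste0("is_a: ", t$is_a))
    if (!is.null(t$part_of)) out <- c(out, paste0("relationship: part_of ", t$part_of))
    if (!is.null(t$regulates)) out <- c(out, paste0("relationship: regulates ", t$regulates))
  }
  out
}

write_fixture_workflow <- function(path, seed, taxid) {
  steps <- list(
    list(plugin = "parse_fasta_gff3", out = "crop",
         params = list(gff3 = "genome.gff3", fasta = "proteins.fasta",
                       taxid = taxid)),
    list(plugin = "parse_tabular", out = "popseq",
         params = list(path = "popseq.tsv", spec = list(
           subject = list(class = "Gene", accession_col = "gene_id",
                          namespace = "ENSEMBL",
                          location = list(attribute = "GenMapLocation",
                                          chromosome_col = "chrom",
                                          begin_col = "cM", unit = "cM",
                                          taxid = taxid)),
           source = "ENSEMBL", taxid = taxid))),
    list(plugin = "parse_obo", out = "go", params = list(path = "mini-go.obo")),
    list(plugin = "parse_obo", out = "to",
         params = list(path = "mini-to.obo", class = "TO")),
    list(plugin = "parse_gaf", out = "gaf", params = list(path = "annotations.gaf")),
    list(plugin = "parse_tabular", out = "qtl",
         params = list(path = "qtl.tsv", spec = list(
           subject = list(class = "QTL", accession_col = "qtl_id",
                          namespace = "GRAMENE",
                          location = list(attribute = "GenMapLocation",
                                          chromosome_col = "chrom",
                                          begin_col = "begin_cM",
                                          end_col = "end_cM", unit = "cM",
                                          taxid = taxid)),
           object = list(class = "Trait", accession_col = "trait_id",
                         namespace = "GRAMENE", name_col = "trait_name"),
           relation = "control", source = "GRAMENE", taxid = taxid))),
    list(plugin = "parse_tabular", out = "snp",
         params = list(path = "snp.tsv", spec = list(
           subject = list(class = "Gene", accession_col = "gene_id",
                          namespace = "ENSEMBL"),
           object = list(class = "SNP", accession_col = "snp_id",
                         namespace = "ENSEMBL",
                         location = list(attribute = "Location",
                                         chromosome_col = "chrom",
                                         begin_col = "pos", unit = "bp",
                                         taxid = taxid)),
           relation = "has_variance", source = "ENSEMBL", taxid = taxid))),
    list(plugin = "parse_tabular", out = "orth",
         params = list(path = "orthologs.tsv", spec = list(
           subject = list(class = "Protein", accession_col = "crop_protein",
                          namespace = "ENSEMBL"),
           object = list(class = "Protein", accession_col = "ref_protein",
                         namespace = "UNIPROT"),
           relation = "ortholog", source = "ENSEMBL"))),
    list(plugin = "parse_tabular", out = "dom",
         params = list(path = "domains.tsv", spec = list(
           subject = list(class = "Protein", accession_col = "protein_id",
                          namespace = "ENSEMBL"),
           object = list(class = "ProtDomain", accession_col = "domain_acc",
                         namespace = "INTERPRO", name_col = "domain_name"),
           relation = "has_domain", source = "ENSEMBL"))),
    list(plugin = "parse_uniprot_min", out = "ref",
         params = list(path = "uniprot_min.tsv")),
    list(plugin = "parse_publications", out = "pubs",
         params = list(path = "abstracts.xml")),
    list(plugin = "union", out = "gskn",
         inputs = list("crop", "popseq", "go", "to", "gaf", "qtl", "snp",
                       "orth", "dom", "ref", "pubs")),
    list(plugin = "accession_map", graph = "gskn"),
    list(plugin = "collapse_equal", graph = "gskn"),
    list(plugin = "colocation_map", graph = "gskn",
         params = list(subject_class = "Gene", region_class = "QTL")),
    list(plugin = "proximity_map", graph = "gskn",
         params = list(subject_class = "SNP", target_class = "Gene", window = 0)),
    list(plugin = "external2go_map", graph = "gskn",
         params = list(path = "external2go.txt")),
    list(plugin = "sequence_map", graph = "gskn",
         params = list(top_k = 10, min_score = 100)),
    list(plugin = "textmine", graph = "gskn",
         params = list(gene_class = "Gene", term_class = "TO")),
    list(plugin = "write_oxl", graph = "gskn", params = list(path = "gskn.oxl")),
    list(plugin = "write_json", graph = "gskn", params = list(path = "gskn.json"))
  )
  yaml::write_yaml(list(seed = seed, steps = steps), path)
  invisible(path)
}
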