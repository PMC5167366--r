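# shared builders for test graphs and corpora

make_located <- function(g, class, chrom, begin, end, unit, taxid = "1",
                         attr = if (unit == "cM") "GenMapLocation" else "Location") {
  upsert_concept(g, class,
                 accessions = list(acc("UC", sprintf("%s-%d", class, kg_concept_count(g) + 1))),
                 attributes = setNames(list(genomic_location(chrom, begin, end, unit, taxid)),
                                       attr))
}

corpus_graph <- function(abstracts) {
  g <- kg_new()
  for (pmid in names(abstracts))
    upsert_concept(g, "Publication", accessions = list(acc("PMID", pmid)),
                   attributes = list(Abstract = abstracts[[pmid]]), source = "PMID")
  g
}

rand_corpus <- function(n, genes, terms) {
  out <- list()
  fillers <- c("plants were grown in pots", "data were analysed",
               "results are shown", "replication was threefold")
  for (i in seq_len(n)) {
    sents <- vapply(seq_len(sample(1:4, 1)), function(s) {
      bits <- sample(fillers, 1)
      if (runif(1) < .5) bits <- paste(bits, sample(genes, 1))
      if (runif(1) < .5) bits <- paste(bits, sample(terms, 1))
      paste0(toupper(substring(bits, 1, 1)), substring(bits, 2), ".")
    }, character(1))
    out[[sprintf("P%03d", i)]] <- paste(sents, collapse = " ")
  }
  out
}
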