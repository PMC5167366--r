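# Default controlled vocabulary for gsknet knowledge networks.
# Concept classes and relation types cover the standard crop-GSKN
# sources: gene models, ontologies, GO annotations, genetics (SNP/QTL),
# homology, protein domains, pathways, phenotypes and literature.
concept_classes:
  - {id: Thing,        label: "Thing"}
  - {id: Gene,         label: "Gene",                     parent: Thing}
  - {id: Protein,      label: "Protein",                  parent: Thing}
  - {id: RNA,          label: "RNA",                      parent: Thing}
  - {id: SNP,          label: "SNP",                      parent: Thing}
  - {id: QTL,          label: "QTL",                      parent: Thing}
  - {id: Trait,        label: "Quantitative Trait",       parent: Thing}
  - {id: TO,           label: "Trait Ontology",           parent: Thing}
  - {id: BioProc,      label: "Biological Process",       parent: Thing}
  - {id: MolFunc,      label: "Molecular Function",       parent: Thing}
  - {id: CelComp,      label: "Cellular Component",       parent: Thing}
  - {id: ProtDomain,   label: "Protein Domain",           parent: Thing}
  - {id: Publication,  label: "Publication",              parent: Thing}
  - {id: Phenotype,    label: "Phenotype",                parent: Thing}
  - {id: Enzyme,       label: "Enzyme",                   parent: Protein}
  - {id: EC,           label: "Enzyme Classification",    parent: Thing}
  - {id: Comp,         label: "Compound",                 parent: Thing}
  - {id: Path,         label: "Pathway",                  parent: Thing}
  - {id: Reaction,     label: "Reaction",                 parent: Thing}
  - {id: Transport,    label: "Transport",                parent: Thing}
  - {id: ProtComplex,  label: "Protein Complex",          parent: Thing}
relation_types:
  - {id: r,                       label: "related to"}
  - {id: encodes,                 label: "encodes",                  parent: r}
  - {id: equal,                   label: "equal",                    parent: r, symmetric: true}
  - {id: ortholog,                label: "ortholog",                 parent: r, symmetric: true}
  - {id: paralog,                 label: "paralog",                  parent: r, symmetric: true}
  - {id: has_domain,              label: "has domain",               parent: r}
  - {id: has_similar_sequence,    label: "has similar sequence",     parent: r, symmetric: true}
  - {id: in_proximity,            label: "in proximity",             parent: r}
  - {id: associated_with,         label: "associated with",          parent: r}
  - {id: control,                 label: "control",                  parent: r}
  - {id: colocated,               label: "co-located with",          parent: r}
  - {id: cross_reference,         label: "cross reference",          parent: r}
  - {id: participates_in,         label: "participates in",          parent: r}
  - {id: has_function,            label: "has function",             parent: r}
  - {id: located_in,              label: "located in",               parent: r}
  - {id: interacts_with,          label: "interacts with",           parent: r, symmetric: true}
  - {id: has_observed_phenotype,  label: "has observed phenotype",   parent: r}
  - {id: published_in,            label: "published in",             parent: r}
  - {id: is_a,                    label: "is a",                     parent: r}
  - {id: part_of,                 label: "part of",                  parent: r}
  - {id: regulates,               label: "regulates",                parent: r}
  - {id: has_variance,            label: "has variance",             parent: r}
  - {id: cooccurs_with,           label: "co-occurs with",           parent: r}
  - {id: catalysed_by,            label: "catalysed by",             parent: r}
  - {id: consumed_by,             label: "consumed by",              parent: r}
  - {id: produced_by,             label: "produced by",              parent: r}
  - {id: activated_by,            label: "activated by",             parent: r}
  - {id: inhibited_by,            label: "inhibited by",             parent: r}
data_sources:
  - {id: ENSEMBL,   label: "Ensembl"}
  - {id: UNIPROT,   label: "UniProtKB"}
  - {id: TAIR,      label: "TAIR"}
  - {id: GO,        label: "Gene Ontology"}
  - {id: TO,        label: "Gramene Trait Ontology"}
  - {id: GRAMENE,   label: "Gramene"}
  - {id: PMID,      label: "PubMed"}
  - {id: INTERPRO,  label: "InterPro"}
  - {id: TM,        label: "Text mining"}
  - {id: UC,        label: "User-contributed"}
attribute_names:
  - {id: TAXID,           kind: text}
  - {id: Chromosome,      kind: text}
  - {id: BEGIN,           kind: integer}
  - {id: END,             kind: integer}
  - {id: Strand,          kind: text}
  - {id: Location,        kind: location}   # physical map, bp
  - {id: GenMapLocation,  kind: location}   # genetic map, cM
  - {id: AA,              kind: sequence}
  - {id: NA_seq,          kind: sequence}
  - {id: Title,           kind: text}
  - {id: Abstract,        kind: text}
  - {id: Description,     kind: text}
  - {id: Score,           kind: decimal}
  - {id: Identity,        kind: decimal}
  - {id: CoCitations,     kind: integer}
  - {id: PMIDs,           kind: text}
  - {id: Aspect,          kind: text}
  - {id: Year,            kind: integer}
evidence_types:
  - {id: IMPD, label: "Imported from database"}
  - {id: M,    label: "Manually curated"}
  - {id: TM,   label: "Text mining"}
  - {id: ACC,  label: "Accession-based mapping"}
  - {id: NAM,  label: "Name-based mapping"}
  - {id: SEQ,  label: "Sequence-based mapping"}
  - {id: COL,  label: "Co-location mapping"}
  - {id: E2G,  label: "External2GO mapping"}
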