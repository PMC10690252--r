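Package: ContextColoc
Title: Colocalization Significance for Genome Annotations under a
    Context-Aware Markov Chain Null Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether two genome annotations (a query and a reference
    set of genomic intervals) overlap more or less than expected by chance.
    Under the null model the query annotation is generated by a two-state
    Markov chain whose transition probabilities change along the genome
    according to a genomic context (for example assembly gaps or GC-content
    classes), so that confounding covariates are absorbed into the null.
    Exact means and variances of the overlap-count and shared-bases
    statistics are computed in (quasi-)linear time via an algebra of
    two-sided interval summaries and converted to Z-scores and
    normal-approximation p-values; an exact dynamic-programming mode
    returns the full null distribution for small reference annotations.
    Includes BED annotation and context readers, a relative-context builder
    for differential enrichment of nested references, a GC-content context
    builder, a sampler for the generative model, and a synthetic-annotation
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: StatisticalMethod, Annotation, GenomeAnnotation, Epigenetics
RoxygenNote: 7.3.3
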