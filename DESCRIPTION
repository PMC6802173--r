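Package: seCircuit
Title: Super-Enhancer Calling and Transcriptional Regulatory Circuitry
    Mapping from Signal-Scored Peak Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for super-enhancer-guided mapping of cell-type-specific
    regulatory networks from called ChIP-seq peaks and quantified expression.
    Implements ROSE-style super-enhancer identification (TSS exclusion,
    12.5-kb stitching, ranked-signal elbow cutoff), hierarchical peak-to-gene
    feature annotation, multi-factor co-occupancy matrices with correlation
    clustering, directed transcription-factor regulatory networks with
    feed-forward/feedback/autoregulatory motif enumeration, moving-average
    enhancer-count analysis, four-class time-course expression classification,
    a cross-dataset case/control dysregulation screen, and binned
    depth-normalized signal profiling around peak centers. A synthetic-data
    module generates peak landscapes with planted super-enhancer clusters,
    multi-factor binding-site universes, archetype time-course expression and
    case/control datasets with planted effects, so the full pipeline runs and
    is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
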