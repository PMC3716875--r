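Package: structscan
Title: Semi-Global RNA Sequence-Structure Scanning with Thermodynamic
    Evidence
Version: 1.0.0
Authors@R:
    person("structscan", "developers", email = "structscan@example.org",
           role = c("aut", "cre"))
Description: Scans long RNA target sequences for occurrences of a
    structure-annotated query by simultaneous alignment and folding in the
    PMcomp/LocARNA lineage of lightweight Sankoff variants.  The target is
    annotated with local base pair probabilities (read from sparse text
    files or computed by a built-in windowed partition-function folder);
    the query is a single sequence or a multiple alignment with a
    consensus secondary structure.  Sequence and thermodynamic-structure
    evidence are scored jointly in a single left-to-right pass whose
    memory is bounded by the base-pair span limit and the query length,
    independent of the target length.  Includes streaming reporting of
    locally maximal, non-dominated occurrences with empirical affine-tail
    E-values, bounded-recomputation traceback, and a synthetic decoy
    benchmark that measures recognition of thermodynamic stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
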