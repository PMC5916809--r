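Package: fusionscape
Title: Gene Fusion Filtering, Validation, Annotation, and Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for interpreting gene fusion calls from bulk
    RNA-seq in cancer cohorts. Harmonizes output from several fusion callers,
    applies a five-rule artifact filter cascade (gene exclusion list,
    self/paralog pairs, panel of normals, read-support FFPM threshold, and
    cross-cancer recurrent-artifact removal), validates calls against
    whole-genome sequencing discordant read pairs, annotates breakpoints with
    transcript region, reading frame, and kinase-domain retention, tests
    fusion-expression associations with Tukey outliers and FDR control,
    profiles mutual exclusivity between fusions and driver mutations,
    matches fusions to a druggability table, and enumerates fusion junction
    neoepitopes with a pluggable MHC affinity predictor. Ships a synthetic
    cohort generator with known ground truth so every stage is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
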