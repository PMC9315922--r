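Package: ighvratio
Title: Mutation Typing and Time-to-First-Treatment Analysis for IGHV
    Somatic Hypermutation in CLL
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the types and quantities of somatic
    mutations in rearranged immunoglobulin heavy-chain variable (IGHV)
    genes relate to clinical course in chronic lymphocytic leukemia.
    Calls nucleotide mutations against germline, classifies each as
    silent (S), conservative replacement (Rc) or non-conservative
    replacement (Rnc) using amino-acid physicochemical class tables
    (hydropathy, volume, chemistry), computes the pseudocounted
    (S+Rc)/Rnc mutation-type ratio and Low/High ratio groups, performs
    exact one-to-one matching on total mutation count, and estimates
    time-to-first-treatment with built-in Kaplan-Meier, log-rank and Cox
    proportional-hazards routines. A synthetic cohort generator emulates
    the immunogenetic and survival structure of real CLL cohorts so the
    whole pipeline can be validated end-to-end without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
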