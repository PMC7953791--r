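Package: ihcdiff
Title: Probabilistic Differential Diagnosis from Immunohistochemistry Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and querying a disease-by-antibody
    immunohistochemistry (IHC) positivity knowledge base and for ranking
    differential diagnoses from binary IHC panels with a naive-Bayes
    posterior. Includes encoding of textbook positivity terms, antibody
    synonym resolution, display grading, a top-k diagnosis ranker with
    probability flooring and missing-data policies, a validation harness
    (case filtering, top-10 hit rates per tumour category, chi-square
    comparison of error rates), and a seeded synthetic generator of
    knowledge bases and labelled case sets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
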