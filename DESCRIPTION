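Package: zhengnet
Title: Symptom Networks and Syndrome Pattern Analysis for Ordinal Clinical
    Inquiry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the pattern of Traditional Chinese Medicine
    syndromes (ZHENG) in clinical inquiry cohorts with ordinal symptom
    grades and binary syndrome labels. Ranks key symptoms per syndrome by
    Fisher's score, builds weighted-mutual-information symptom networks
    from syndrome positive sets, identifies dynamically increased and
    decreased symptom interactions by a label-shuffling permutation test,
    relates syndromes through Tanimoto co-occurrence networks, and
    benchmarks per-syndrome classifiers (naive Bayes, tree-augmented naive
    Bayes, support vector machine, decision tree) under repeated
    cross-validation. Includes a synthetic cohort generator with planted
    ground truth for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, igraph, e1071, rpart,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Network, Classification, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 'AllGenerics.R' 'AllClasses.R' 'cohort-io.R'
    'synthetic-cohort.R' 'fisher-score.R' 'wmi-network.R' 'topology.R'
    'permutation.R' 'classifiers.R' 'pipeline.R'
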