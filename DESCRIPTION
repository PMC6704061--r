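Package: hergsel
Title: hERG Inhibition Classification with NSGA-II Descriptor Selection
Version: 0.1.0
Authors@R: person("hergsel", "maintainers", email = "hergsel@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building binary hERG (human Ether-a-go-go Related
    Gene potassium channel) inhibition classifiers from heterogeneous assay
    databases. Curates and deduplicates IC50 / percent-inhibition records
    into binary activity labels with majority-agreement conflict resolution,
    filters descriptor tables by variance and pairwise correlation, trims
    the majority class by fingerprint clustering, selects descriptor subsets
    with the multi-objective genetic algorithm NSGA-II wrapped around a
    class-weighted RBF-kernel support vector machine scored by 5-fold
    cross-validated Cohen's kappa, recombines Pareto-front descriptor sets
    with structural fingerprints, and assesses applicability domain by
    maximum Tanimoto similarity to the training set. Includes a synthetic
    data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
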