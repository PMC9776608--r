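Package: andronet
Title: Dynamic Modelling of the AR/NF-kB Crosstalk Network and Gene Set
    Enrichment Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating an almost-linear dynamic network of the
    androgen receptor (AR), PI3K, PTEN, p65 NF-kB, IkB and c-Myc in prostate
    cancer cells, including fixed-point and eigenvalue stability analysis, a
    positivity-constrained explicit Euler integrator with scheduled in-silico
    drug perturbations, and the three-phase androgen-ablation / NF-kB-inhibition
    / PI3K-inhibition scenario. Also implements the transcriptomic scoring
    statistics used alongside the model: signed log10 p-value gene ranking,
    differential-expression filtering, pre-ranked gene set enrichment with a
    gene-permutation null, hypergeometric overrepresentation, gene-set activity
    scoring with a Wilcoxon rank-sum comparison, and a synthetic two-group
    expression generator with planted gene sets so that every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
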