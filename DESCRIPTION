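Package: nacstrat
Title: Biomarker Screening and Risk Stratification for Neoadjuvant
    Chemotherapy Response in Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building predictive models of resistance to
    neoadjuvant gemcitabine/cisplatin chemotherapy in muscle-invasive
    bladder cancer from expression and immunohistochemistry data. Provides
    a permutation-controlled expression screen (signal-window filter, AUC
    ranking, Mann-Whitney testing, permutation false-discovery-rate
    control), hierarchical clustering of samples on a screened signature,
    two-round adaptive-boosting selection of a binary marker pair with
    repeated cross-validation stability, exhaustive-search classification
    trees for risk stratification over clinical and marker predicates,
    ordinal association statistics (Goodman-Kruskal gamma, Fisher's exact
    test, Cohen's kappa, Kruskal-Wallis, multivariable logistic
    regression), and seeded synthetic-data generators with known ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
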