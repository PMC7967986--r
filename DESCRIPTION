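Package: otulda
Title: Microbial Subgroup Discovery from OTU Tables via Latent Dirichlet
    Allocation and Dirichlet Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns latent microbial subgroups from 16S rRNA OTU count
    tables with a collapsed-Gibbs latent Dirichlet allocation sampler,
    selects the number of subgroups by k-fold cross-validated held-out
    perplexity, and relates the per-sample subgroup probabilities to
    habitual-diet and metabolic-disease covariates with Dirichlet
    regression under Bonferroni control. Includes the standard
    companion analyses: abundance/prevalence OTU filtering, genus-level
    collapse of subgroup-OTU probabilities, Ward clustering of
    subgroups, summed subgroup probabilities over externally defined
    OTU sets, enterotype-style clustering by Jensen-Shannon divergence
    with partitioning around medoids, and multinomial logistic
    regression of cluster membership. A synthetic-data module generates
    OTU tables from the same generative model with recorded ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    nnet,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
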