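Package: spfldyn
Title: Senescence and Entrenchment of Alleles on Dynamic Single-Position
    Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time simulation of amino-acid site evolution along a
    rooted phylogeny under static and dynamic single-position fitness
    landscapes (SPFLs), extraction of substitution subtrees from per-node
    ancestral states, age-dependent allele-replacement summary statistics,
    approximate Bayesian computation (rejection with local ridge-regression
    adjustment) for the rate of change of the resident allele's fitness and
    the fraction of affected alleles, and a per-allele binomial logistic
    detector of senescing and entrenched alleles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
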