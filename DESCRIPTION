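Package: enudamage
Title: Damage Probability, Genome Saturation and Essential-Gene Inference
    for ENU Mutagenesis Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for forward-genetics mutagenesis programs in the mouse.
    Implements pedigree-aware filtering of N-ethyl-N-nitrosourea (ENU)
    induced mutations, a method-of-moments mixture estimator of the
    fraction of mutations per predicted-effect class that truly damage
    protein function (with bootstrap confidence intervals), exact and
    Monte Carlo calculation of per-gene homozygous-damage probabilities
    and cumulative genome saturation, an in-silico breeding simulation
    that estimates the essential-gene fraction of the genome, binomial
    comparison of phenotype-linkage rates between essential and
    non-essential genes, and a synthetic pedigree generator with known
    ground truth for validating the whole stack.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
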