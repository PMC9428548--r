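Package: kinesin13
Title: Ancestral and Consensus Kinesin-13 Motor Domains with
    Depolymerization Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to infer reference motor-domain sequences for the
    microtubule-depolymerizing kinesin-13 family and to analyze the kinetic
    measurements used to characterize them. Implements maximum-likelihood
    marginal ancestral sequence reconstruction under the WAG amino-acid
    substitution model (Felsenstein pruning with separate binary-character
    indel reconstruction), most-common-residue consensus inference with
    BLOSUM62 tie resolution, reverse translation against a host codon-usage
    table, estimators for microtubule depolymerization rates, censored
    single-molecule dwell-time kinetics, ATPase turnover and ATP-per-tubulin
    coupling stoichiometry, plus seeded synthetic-data generators that close
    the loop on every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
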