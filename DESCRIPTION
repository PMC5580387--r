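Package: ctvert
Title: Classification of Cervico-Thoracic Transitional Vertebrae and Exact
    Incidence Statistics
Version: 1.0.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based scoring and classification of last-cervical (C7),
    transitional cervico-thoracic (C/T), and first-thoracic (T1) vertebrae
    from a 12-character osteological scheme, with exact small-sample
    statistics for comparing the incidence of transitional vertebrae
    between populations: hypergeometric enumeration, Fisher's exact test
    with the minimum-likelihood two-sided rule, Clopper-Pearson binomial
    confidence intervals, a conditional maximum-likelihood odds ratio, and
    seeded Monte-Carlo calibration (type-I error) and power estimation on
    synthetic specimen populations.  Ships curated specimen fixtures
    (Late Pleistocene woolly rhinoceros C7 vertebrae and extant
    rhinocerotid comparative skeletons) and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
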