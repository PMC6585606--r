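Package: limbselect
Title: Stochastic Two-Site Dynamics of Perseverative Limb Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates hand choice as a competition between two
    mutually inhibiting activation sites, one per limb, with
    handedness expressed as an asymmetry in cross-inhibition
    strength, trial-to-trial motor memory as an accumulating input,
    and additive noise integrated by a stochastic Euler scheme.
    Includes the six-trial training/neutral perseveration protocol,
    Monte-Carlo cohort simulation with age-group parameter presets,
    and categorical statistics for behavioral records (handedness
    classification, preferred-hand transform, chi-squared and
    McNemar tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
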