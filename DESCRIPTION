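Package: iceclock
Title: Dating Marine Ice and Calibrating Microbial Evolutionary Rates
Version: 0.1.0
Authors@R: person("B15", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two linked computations for time-separated samples preserved in
    Antarctic ice-shelf marine ice. A Lagrangian layer-tracking model dates
    marine ice accreted beneath an ice shelf from flowline transit time,
    basal accretion/melt rates and vertical strain thinning, producing
    age-depth profiles with melt-rate-driven uncertainty. An evolutionary
    rate calibration turns read-mapping SNP counts and protein alignments
    separated by a known time span into rates (SNPs per Mb per century and
    amino-acid substitutions per 100 residues per century), with the
    supporting Jukes-Cantor distance, neighbor-joining, bootstrap and
    Nei-Gojobori dN/dS machinery. A synthetic-data module generates velocity
    fields, forcing scenarios with closed-form solutions, divergent genomes
    with planted substitutions, and simulated reads with truth alignments so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
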