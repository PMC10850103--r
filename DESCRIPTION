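Package: splicescope
Title: Enumeration, Identification and Quantitative Analysis of
    Proteasome-Generated Spliced and Non-Spliced Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying proteasome-catalyzed peptide hydrolysis and
    splicing in in vitro digestions of single proteins. Provides closed-form
    and brute-force counting plus enumeration of the non-spliced, cis- and
    homologous trans-spliced peptide search space of a substrate protein;
    origin-aware semi-supervised rescoring of peptide-spectrum matches with
    target-decoy q-values, posterior error probabilities and stratified group
    FDR; spectral-angle and retention-time similarity features with a
    deterministic mock spectrum predictor; label-free MS1 kinetic
    quantification filtering; sequence-preference analytics (site-specific
    cleavage and splicing strengths, simulated background databases,
    Jensen-Shannon divergence logos, coverage profiles and hotspot analysis);
    a ground-truth benchmark builder with precision-recall evaluation; and a
    synthetic-data generator that makes the full pipeline runnable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
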