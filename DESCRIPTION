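Package: pcbscreen
Title: Suspect Screening, Quantification and Chirality Statistics for
    PCB95 Metabolites in High-Resolution Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semitargeted screening of polychlorinated biphenyl
    (PCB95) metabolites in centroided high-resolution mass spectrometry
    peak lists. Enumerates candidate metabolites with a biotransformation
    rule engine (oxidation, sulfation, sulfonation, methylation, reductive
    dechlorination), computes exact monoisotopic ion masses and chlorine
    isotope envelopes, matches and confirms candidates by mass tolerance,
    isotope-pattern score and neutral-loss fragments, and assigns
    identification confidence levels. Also implements internal-standard
    GC-MS/MS quantification with surrogate-recovery correction and
    blank-based detection limits, enantiomeric-fraction computation for
    atropisomer peak pairs, profile similarity (cosine), and two-way
    ANOVA with Bonferroni-corrected pairwise comparisons. A synthetic
    study generator with full ground truth makes every pipeline stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'pcbscreen-package.R'
    'constants.R'
    'AllClasses.R'
    'formula.R'
    'rules.R'
    'isotopes.R'
    'screening.R'
    'quant.R'
    'chirality.R'
    'profilestats.R'
    'synthetic.R'
    'pipeline.R'
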