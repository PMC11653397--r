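---
title: "Methods: suspect screening and statistics for PCB95 metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suspect screening and statistics for PCB95 metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbscreen)
```

# Scope and model

`pcbscreen` implements a semitargeted screen for metabolites of PCB95
(2,2′,3,5′,6-pentachlorobiphenyl) in centroided, negative-mode LC–HRMS
peak lists, plus the targeted-quantification and statistics layers that
typically accompany such a study. The pipeline is: generate a suspect
list by applying biotransformation rules to the parent formula; match
each candidate's theoretical `[M−H]⁻` m/z against per-sample MS1 peaks
at a ppm tolerance; confirm hits by the chlorine isotope pattern and,
where PRM scans exist, by diagnostic neutral losses; keep candidates
detected in a strict majority of samples; normalize intensities to a
spiked volume corrector (PFOS) and sample wet mass; and analyse the
resulting metabolite levels with enantiomeric fractions, cosine profile
similarity and two-way ANOVA.

## The biotransformation rule engine

A candidate is an elemental composition plus a metabolite class —
positional isomers are deliberately not distinguished, because
reversed-phase LC cannot resolve them reliably and several hydroxylated
isomers coelute. Rules are signed element-count deltas with
constraints:

| rule | delta | biology | constraint | default cap |
|------|-------|---------|-----------|-------------|
| `OX` | +O | P450 hydroxylation | phase-I only (not after conjugation) | 3 |
| `SULF-O` | +SO₃ | phenol O-sulfation (SULT) | ≥ 1 prior `OX` | 1 |
| `SULFON-C` | +SO₃ | ring C-sulfonation (mercapturic pathway) | unoxidized core | 1 |
| `METH` | +CH₂ | catechol O-methylation (COMT) | ≥ 2 prior `OX` | 1 |
| `DECHLOR` | −Cl +H | microbial reductive dechlorination | ≥ 1 Cl, phase-I only | 2 |

Three constraints deserve comment, since a formula alone cannot carry
them:

- **`METH` requires two prior oxidations.** COMT acts on catechols
  (vicinal diols). Element counts cannot see vicinal positioning, so
  the requirement is encoded on the chain's provenance instead — a
  methylation is only generated for candidates whose history contains
  at least two hydroxylations.
- **Conjugation is terminal.** Phase-II products (sulfates, sulfonates,
  methylated catechols) are excreted rather than re-oxidized on this
  pathway. Allowing `OX` after `SULFON-C` would also create a second
  candidate with the *same* formula as the O-sulfate class,
  which would make every sulfate detection spuriously ambiguous.
- **`SULFON-C` fires only on the unoxidized core**, because the ring
  sulfonate class is a parent-ring product and an oxidized variant
  again duplicates the O-sulfate compositions.

The closure is breadth-first with per-rule caps and a chain-length cap
(default 6); candidates are deduplicated by (formula, class) and the
shortest provenance is kept, which makes the output independent of rule
ordering (a property the test suite checks by reversing the rule list).
The caps (`OX` ≤ 3, `DECHLOR` ≤ 2, one conjugation) cover the full
detectable class catalogue — classes 1.1 through 8 — without
combinatorial blow-up; they are arguments, not constants.

## Exact masses

Monoisotopic masses are principal-isotope sums over a pinned table
(¹²C = 12 exactly, ¹H = 1.00782503, ¹⁶O = 15.99491462,
³⁵Cl = 34.96885268, ³²S = 31.97207117, ¹⁹F = 18.99840316 Da), and the
anion m/z adds one electron mass (0.00054858 Da) per negative charge.
Reference `[M−H]⁻` values for these metabolite classes are printed to
five decimals; the chosen table reproduces all nine to within
2 × 10⁻⁵ Da, which is how the convention was fixed — sources of such
tables rarely state their electron-mass handling, and the package
documents the convention rather than assuming it. A guard test verifies
that *omitting* the electron term breaks the agreement (≈ −0.55 mDa on
every anion), so the correction cannot silently regress.

## Isotope envelopes and the pattern score

Fine-structure distributions are exact multinomial expansions computed
by convolution of per-element distributions (binary exponentiation over
atom counts; entries merged within 10⁻⁶ Da; abundances below 10⁻⁶
pruned — that threshold keeps Cl₅ envelopes exact to the printed
precision while bounding entry counts). An exhaustive per-atom
isotopologue enumeration serves as the oracle in tests for molecules
small enough to enumerate.

For matching, the fine structure is aggregated to *nominal* unit-Da
bins at integer offsets from the monoisotopic peak, because
chlorinated-compound patterns are conventionally read as
M : M+2 : M+4 : M+6 ratios, not fine structure. The full-molecule
envelope of C₁₂H₄Cl₅O⁻ computed this way gives
62.1 : 100 : 64.6 : 21.0, i.e. the textbook 62 : 100 : 65 : 21
pentachloro pattern after rounding. Whether that reference ratio
includes ¹³C contributions is ambiguous — a Cl₅-only binomial gives
62.5 : 100 : 60.0 : 16.0, so M+4 and M+6 distinguish the two readings —
and the package computes the full-molecule pattern, which reproduces
all four printed values within one intensity unit.

The **pattern score** is the cosine between the theoretical relative
intensities and the observed intensities matched within the ppm
tolerance at each bin's abundance-weighted m/z (missing peaks
contribute zero). Scoring is restricted to the top four theoretical
peaks by default — the visually diagnostic chlorine peaks — and a
missing monoisotopic peak forces score 0 with a flag. The default
acceptance threshold of 0.95 is a configuration default validated on
synthetic data (no numeric criterion exists to inherit): planted full
envelopes score ≥ 0.99 even at 1.5 ppm mass error, while
monoisotopic-only decoys and chlorine-free contaminants fall well
below.

## Screening decisions

- **Tolerance**: 5 ppm on MS1 and MS2 matching, the study's stated
  window.
- **Feature building**: in-tolerance peaks are grouped into
  rt-contiguous features with a maximum gap of 0.2 min and the apex
  (most intense peak) is recorded. The original processing happened
  inside vendor software with no stated algorithm; this is the simplest
  defensible reconstruction and the gap is configurable.
- **Ambiguity**: two candidates claiming the same apex peak are both
  reported and flagged, not resolved — coeluting indistinguishable
  isomers are a real feature of these data.
- **Confidence levels**: isotope confirmation is required for detection;
  any confirmed neutral loss (HCl for chlorinated phenols, SO₃ for
  O-sulfates, •CH₃ for methylated catechols; loss masses computed from
  the same atomic table) upgrades confidence from level 3 to level 2.
  Ring sulfonates have no diagnostic loss and stay level 3.
- **Majority rule**: retained iff detected in strictly more than 50 %
  of study samples. Whether the frequency should be counted before or
  after isotope confirmation is not specified anywhere; the default is
  *after* (a hit that fails isotope confirmation is not a detection),
  with `frequency_on = "matched"` exposed for the other reading.
- **Normalization**: `intensity / (PFOS intensity × wet mass)`, with
  blank-flagging when a candidate's median blank level exceeds 10 % of
  its study median (the blank rule is a configurable default; parallel
  blanks are standard practice but no numeric rule was stated).

## Quantification

Internal-standard quantification:
`c = (A_analyte/A_IS)/RRF × m_IS/m_sample`, divided by the matching
surrogate's fractional recovery (recoveries ≤ 0 or above a 1.5 cap are
rejected). Unknown metabolites without standards use the *average* RRF
of their MRM transition group — mono-hydroxylated unknowns average the
three mono-OH standards, di-hydroxylated unknowns use the single di-OH
standard — and are flagged `estimated`. MDL = mean(method blanks) +
3 SD and LOQ = mean(tissue blanks) + 10 SD are standard-practice
formulas chosen here explicitly (only blank-based determination was
stated). Below-LOQ values are flagged rather than censored, and enter
statistics as LOQ/2 by default (LOQ/√2 and zero are offered) — the
choice is exposed because censoring policy was not stated and it
affects group means.

## Chirality and statistics

`EF = A_E1/(A_E1+A_E2)`; the racemic QC band is the standard's EF
0.498 ± 3 × 0.004 (the standard's SD; no acceptance band was stated, so
3 SD is the package's choice). The mapping of elution order to absolute
configuration (E2 = aS) is carried as metadata only. A
perpendicular-drop integrator for two-Gaussian synthetic chromatograms
is provided for fixture generation; real peak areas are always inputs.

cos θ is the normalized dot product over a shared metabolite panel,
computed on group-mean profiles by default (group-level comparison),
with per-sample use possible. The two-way sex × genotype ANOVA uses
Type-II sums of squares — group sizes of 5–7 are typical and
unbalanced, and Type II tests main effects without order dependence;
the original software default is unknowable, so the choice is made
explicitly. Pairwise cell comparisons use t statistics on the pooled
residual mean square with Bonferroni adjustment (p × number of
comparisons, capped at 1), significance at p < 0.05. Log-transformation
before ANOVA is exposed as an option and off by default (no statement
either way; concentrations are analysed on their native scale).
Degenerate designs are handled explicitly: a constant response reports
F = 0, p = 1; a single-level factor collapses to the one-way ANOVA on
the other factor (where F equals the squared two-sample t statistic).

# The synthetic-data generator

`generateStudy()` emulates the study design: 2 sexes × 3 genotypes
× 6 animals, 15 planted chromatographic species across the nine
candidate compositions (several classes elute as 2–3 isomers at
distinct retention times), log-normal abundances (median 10⁶ arbitrary
units, geometric SD 2.5) with multiplicative group effects (F × 1.5,
KO × 2, KI × 0.7 — chosen to make ANOVA effects detectable at realistic
sizes), Gaussian m/z error of SD 1.5 ppm (consistent with sub-5-ppm
observed errors on a 70k-resolution instrument), retention-time jitter
of SD 0.05 min, MS2 neutral-loss fragments emitted with probability 1
for the fragment-bearing classes (1.1–4) and 0 for classes 5–8
(mirroring which classes ever show PRM fragments), a PFOS
volume-corrector ion in every run, 200 decoy peaks per sample placed
uniformly in 150–1000 m/z but never within 25 ppm of any suspect, and
parallel blanks containing only decoys and PFOS.

`generateGcTables()` inverts the quantification model: areas are
constructed as
`A = c × m_sample × recovery × RRF × A_IS / m_IS`, so noise-free tables
round-trip to the planted concentrations at machine precision — the
closed-loop oracle for the quantification stage. Unknown analytes are
constructed to respond exactly at their transition group's average RRF,
making the group-average estimator exact in the noise-free case.
Multiplicative area noise is *mean-one* log-normal
(`exp(N(−σ²/2, σ²))`), so noise perturbs but does not bias the
recovered concentrations; GC concentration medians (parent 80 ng/g,
individual OH metabolites 300–500 ng/g) sit in the reported
order-of-magnitude ranges. Atropisomer area pairs split a total area by
each group's configured EF (defaults spanning 0.39–0.45, with racemic
0.5 available for QC fixtures).

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: chromatographic peak shapes and
integration error, ion suppression and matrix effects,
resolution-dependent isotope fine structure, retention-time drift
across samples, and real blank contamination structure. The closed
loop demonstrates that the pipeline's logic is correct, not that the
instrument model is.

# Numerical choices and problem sizes

- All randomness flows from one integer seed per generated study;
  identical seeds give identical output, byte for byte.
- Convolution merges masses within 10⁻⁶ Da and prunes abundances below
  10⁻⁶ (both arguments); envelope abundances are left unrenormalized
  after pruning so the pruning loss stays visible (tests bound it).
- Ties in feature apexes resolve to the first maximum; candidate tables
  sort classified classes first.
- Test and acceptance problem sizes are chosen to exercise the
  contracts at comfortable runtime: the screening closed loop runs the
  full 36-sample, 15-species study; quantification bias is measured
  over 1000 replicates of a 6-sample study under 10 % noise; the
  Bonferroni null simulation uses 10,000 replicates of a 2 × 3 design
  with n = 3 per cell.

# Known limitations

- Only deprotonated ions are modeled; the charge argument is
  extensible but the pipeline fixes z = −1.
- No structure handling (SMILES), no positional-isomer prediction, and
  no mass generation for classes outside the rule set (arene oxides,
  glucuronides, dihydrodiols, methyl sulfones) beyond their absence
  being documented.
- No profile-mode centroiding, no cross-sample retention-time
  alignment, and no chromatogram integration from raw signals — peak
  lists and areas are the interface.
- The ANOVA layer offers Bonferroni only; no mixed models.
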