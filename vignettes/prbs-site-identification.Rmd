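---
title: "Identifying PAR-crosslinked RNA-binding sites: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying PAR-crosslinked RNA-binding sites: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parlock)
```

## The adduct mass model

After metabolic labeling with 4-thiouridine (4SU) or 6-thioguanosine (6SG),
UVA crosslinking and complete chemical digestion of the RNA, a crosslinked
peptide carries exactly one adduct in one of two forms.  Both have lost
H₂S (the loss accompanies the crosslinking photochemistry itself, so no
H₂S-retaining species are modeled):

| PAR | form | composition | nominal Δm |
|-----|------|-------------|-----------|
| 4SU | base | C₄H₂N₂O | 94 |
| 4SU | nucleoside | C₉H₁₀N₂O₅ | 226 |
| 6SG | base | C₅H₃N₅ | 133 |
| 6SG | nucleoside | C₁₀H₁₁N₅O₄ | 265 |

For both PAR types, nucleoside − base = C₅H₈O₄ (ribose, 132.0423 Da)
exactly, by composition arithmetic.  A crosslinked Cys escapes the fixed
iodoacetamide carbamidomethylation, so its variable-modification delta is
the generic delta minus C₂H₃NO (−57.0215 Da); `adduct_delta()` enforces
`delta(C) + 57.0215 = delta(non-Cys)` by construction.  Atomic masses are
the standard monoisotopic values to ≥ 9 decimals, tabulated in
`R/chem_model.R`; residue masses are derived from residue elemental
compositions through the same `mass_of()` arithmetic rather than a second,
independent table, so a single source of truth covers peptides, fragments
and adducts.  m/z ↔ neutral conversions use the proton mass
(1.007276 Da), not the hydrogen atom, per MS convention.

Adduct definitions can be extended from a plain-text table
(`read_adduct_config()`), so a future photoactivatable analog only needs a
formula, not code.

## The search

The central chemical fact is asymmetry between the MS levels: nucleoside
adducts survive at MS1 but lose their ribose nearly completely during HCD,
so site-covering MS2 fragments of *both* forms appear base-form.  The
search therefore:

1. duplicates every scan, subtracting `132.0423 / z` from the precursor
   m/z of the copy (`correct_scan()`),
2. searches both copies with a single base-form variable modification
   (at most one per peptide) against a concatenated target–decoy database
   (full protein reversal, `XXX_` accession prefix), and
3. keeps one best PSM per scan across both copies, so scan duplication
   cannot inflate PSM counts.  A corrected-copy winner is annotated as the
   nucleoside form.

The `conventional` mode — the baseline the duplication strategy is measured
against — searches only uncorrected precursors with base *and* nucleoside
variable modifications and applies each searched delta to the fragments
as-is.  For a nucleoside-form spectrum its site-covering theoretical
fragments are then 132 Da too heavy, halving the usable fragment evidence
and, more importantly, removing most of the ions that discriminate
neighboring candidate sites; such PSMs are more often site-ambiguous and
are discarded downstream.  This is the mechanism behind the corrected
search's higher nucleoside-site yield in the acceptance checks.

### Scoring

An external engine's spectrum-level E-value is replaced by a deterministic
surrogate: the raw score is the number of matched theoretical b/y ions
weighted by `log10(1 + relative intensity)`, and the significance is the
exact binomial tail `P(X ≥ k)` for `k` matches out of `n = 2(L−1)`
fragments, with per-fragment match probability
`p = 2 · frag_tol · n_peaks / (observed m/z span)`, capped below 1 and
floored at 1e-300 so `−log10` stays finite.  Zero matches or an empty peak
list give significance 1, and such candidates are never reported.  Any
order-preserving surrogate leaves the downstream pipeline unchanged; this
one is desk-computable, which the test suite exploits by comparing it
against a hand-summed binomial tail.

Ties are broken deterministically: target before decoy, unmodified before
modified, lexicographically smaller peptide, smaller site index,
uncorrected before corrected.  An unmodified candidate is only evaluated
against the uncorrected copy — an unmodified match to a ribose-corrected
precursor has no chemical interpretation, and the PSM contract equates
"corrected" with "nucleoside form".

### Tunable parameters

| parameter | default | units | rationale |
|-----------|---------|-------|-----------|
| `prec_ppm` | 10 | ppm | Orbitrap-class MS1 accuracy |
| `frag_tol` | 0.02 | Da | 15k-resolution centroided HCD MS2 |
| `missed_cleavages` | 2 | – | field-standard tryptic setting |
| `length_range` | 6–40 | residues | field-standard tryptic setting |
| `charge_range` | 2–7 | – | acquisition charge-state screen |
| recalibration window | ±5 | ppm | instrument drift envelope |
| UMC `mass_ppm` | 10 | ppm | conservative feature linking |
| UMC `rt_gap` | 60 | s | conservative feature linking |
| UMC FDR `alpha` | 0.01 | – | site-level confidence target |

The engine-internal tolerances of the original workflow are not published;
the defaults above are declared choices, all configurable per call.

## Postprocessing

*Recalibration.*  The precursor-error center is the mean ppm error of
high-confidence PSMs; before q-values exist, "high-confidence" means target
PSMs in the best 10% of significance.  An empty high-confidence set centers
at 0 ppm with a warning.  PSMs outside ±5 ppm of the center are dropped.

*Exclusions.*  Unmodified PSMs, PSMs localized to a C-terminal Lys/Arg
(indistinguishable from a missed-cleavage artifact), and PSMs whose best
site is tied at equal significance are discarded.

*UMCs.*  Single-linkage clustering over (uncorrected neutral mass within
10 ppm) ∧ (RT gap ≤ 60 s) emulates marking individual XIC peaks as unique
mass classes.  Distinct elution peaks of the same peptide — distinct
crosslink isoforms — stay separate; base and nucleoside precursors of one
peptide differ by 132 Da and can never co-cluster at ppm scale.  Because
clustering operates on neutral mass, charge states of one species
co-cluster.

*Localization.*  One site per UMC, scored as the `−log10(significance)`
share of the winning site; shares over observed sites sum to 1.  A UMC
whose members all have significance 1 carries no information and is dropped
with a warning.  One localization per UMC (not per peptide) lets several
UMCs of the same peptide report different residues, so multiple sites per
peptide are representable.

*FDR.*  UMCs inherit the decoy status of their best member; the estimate at
rank r is `#decoys/#targets`, q-values are the running minimum from the
worst rank, and targets with q < 0.01 are accepted.  The test suite checks
the q-values against a brute-force cutoff-scan oracle.

*Quantification.*  MostAbundant surrogate: the maximum member precursor
intensity, with absent intensities treated as 0 and flagged — MGF input
carries no MS1 profiles, so true XIC areas are out of reach by design.

*Collapse.*  Peptide sites map to protein coordinates through the digestion
provenance (1-based, validated against the database sequence); shared
peptides expand to every protein-group member with the group id noted.

## The synthetic-data generator

`simulate_dataset()` is the package's benchmarking instrument, not a
fixture: it emulates exactly the structure the method assumes.  Study
conditions (the defaults of `sim_config()`): 200 proteins of 60–120
residues drawn from human-like amino-acid frequencies, 300 planted
crosslink sites with propensity weights favoring Trp/Tyr/Phe/His/Cys, 40%
nucleoside form, 30% in-source fragmentation (nucleoside sites additionally
emitting a co-eluting base-form precursor), Poisson-distributed XIC-like
occurrences (mean 2) jittered ±20 s, fragment sampling efficiency 0.9,
Gaussian 3 ppm precursor error, 0.004 Da fragment jitter, log-normal
intensities, 5 noise peaks per peptide spectrum, 100 uncrosslinked
background peptide spectra and 150 pure-noise scans.  Site-covering MS2
fragments always carry the base-form delta — the generator encodes the
ribose neutral loss.  Planted sites avoid the peptide C-terminal K/R
because the exclusion rules discard such localizations categorically.

A site-level abundance is drawn at planting time and spectra scatter
around it, so two simulations sharing `seed` but differing in
`spectrum_seed` are technical replicates with correlated quantities —
the basis of the replicate-correlation summary.

What the generator does **not** model: chromatographic peak shapes, isotope
envelopes, co-isolated chimeric spectra, semi-tryptic peptides, multiply
modified peptides, and fragment charge states above 1.  Passing the
recovery benchmarks therefore demonstrates correctness of the search logic
and calibration machinery under the stated noise model, not performance on
raw instrument data.

### Problem sizes and calibration design

The acceptance checks run the default 200-protein/300-site conditions for
recovery and for the corrected-vs-conventional comparison.  The FDR
calibration study uses ten independent simulations of 50 proteins and 60
sites, each flooded with 1,200 dense pure-noise scans (150 peaks) so that
incorrect candidate matches actually reach the acceptance boundary; the
pooled realized false-discovery proportion is compared to the 1% target
within three binomial standard errors.  At this scale the UMC FDR is
conservative — the ambiguity exclusions remove most random matches before
the decoy competition — and the realized proportion sits below the
estimate.  The survey profiles use 25-protein/40-site all-nucleoside
simulations, and the replicate comparison 60 proteins/80 sites.

## Known limitations

* The significance surrogate is calibrated for ranking, not for absolute
  error rates; only the target–decoy q-values carry error-rate meaning.
* Peptides occurring multiply within one protein are anchored at their
  digestion-provenance coordinates.
* `precursor_delta_profile()` is a deliberately simplified open-search
  surrogate (best fragment-count candidate, 1-Da bins); it reproduces the
  offset histogram's shape, not an engine's full open search.
* mzML input is not parsed; MGF (plus an RT-from-index fallback) is the
  supported spectrum source, and quantification quality is bounded by what
  the MGF carries.
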