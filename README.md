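# parlock

Identification of photoactivatable-ribonucleoside (PAR) crosslinked
RNA-binding sites (RBSs) at single-amino-acid resolution from tandem mass
spectra.

## The problem

Proteins crosslinked to 4-thiouridine (4SU) or 6-thioguanosine (6SG) in
cellular RNA and digested chemically (HF) down to a single-residue adduct
carry one of two precursor mass shifts per PAR type: the **base** form
(4-thiouracil / 6-thioguanine, minus H₂S) or the **nucleoside** form (base
plus ribose).  During HCD fragmentation, nucleoside adducts lose the ribose
(C₅H₈O₄, 132.0423 Da) almost completely, so at the MS2 level *both* forms
look like the base form.  A conventional closed search that treats the two
forms as independent variable modifications therefore mispredicts the
site-covering fragments of nucleoside precursors by 132 Da and loses them.

`parlock` implements the remedy: every MS2 scan is **duplicated**, one copy
keeping its precursor mass and one with the ribose mass subtracted
(`m/z − 132.0423/z`).  Both copies are searched against a reversed-sequence
target–decoy database with a *single* base-form variable modification
(nominal deltas 94/226 Da for 4SU base/nucleoside, 133/265 Da for 6SG;
crosslinked Cys is additionally adjusted by −57 Da because it escapes the
fixed carbamidomethylation).  One best PSM per scan is kept — a win for the
corrected copy means the precursor was the nucleoside form.  PSMs are then:

1. filtered to a ±5 ppm window around the recalibrated precursor-error
   center,
2. stripped of unmodified, C-terminal-K/R-localized and ambiguous matches,
3. clustered into unique mass classes (UMCs; single-linkage over neutral
   mass ppm and retention time),
4. assigned one site localization per UMC with score
   `Σ −log₁₀(significance) at the site / Σ −log₁₀(significance) in the UMC`,
5. thresholded at a UMC-level target–decoy FDR < 0.01, and
6. quantified (MostAbundant precursor intensity) and collapsed to protein
   coordinates.

Match significance is an exact binomial tail probability of hitting `k` of
`n` theoretical b/y fragments by chance given the spectrum's peak density —
a deterministic, order-preserving stand-in for an engine E-value.

The package also provides the adduct-characterization survey (MS1
precursor-delta and MS2 y-ion nominal-mass profiles, which reveal the
base/nucleoside pair and the 132 Da gap), a seeded synthetic-data generator
reproducing the adduct chemistry for end-to-end benchmarking, and
dataset-level summaries (normalized amino-acid site frequencies, dataset
overlap, replicate quantification correlation).

## Worked example

```r
library(parlock)

round(adduct_delta("4SU", "base", "W"), 4)        # 94.0167
round(adduct_delta("4SU", "nucleoside", "W"), 4)  # 226.059

sim <- simulate_dataset(sim_config(seed = 42, n_proteins = 30, n_sites = 40,
                                   n_background = 20, n_noise_spectra = 30))
res <- prbs_id(sim$spectra, sim$database, search_params("4SU", "prbs"))
head(res$sites[, c("accession", "position", "residue", "n_umcs",
                   "loc_score", "quant", "q_value")], 4)
#>   accession position residue n_umcs loc_score  quant q_value
#> 1   SYN0001       97       C      1         1  54969       0
#> 2   SYN0002       71       A      1         1 305929       0
#> 3   SYN0003       15       H      2         1 308370       0
#> 4   SYN0004       49       G      1         1 525171       0

evaluate_recovery(res$sites, sim$truth, res$umcs)[
  c("recall", "precision", "false_localization_rate")]
#> recall 0.975   precision 1   false_localization_rate 0
```

Each `sites` row is one protein residue accepted as an RNA-binding site:
its position and residue letter, the number of supporting UMCs, the
localization score (1 = undisputed within its UMCs), the label-free quant
value and the UMC-level q-value.  On this 40-site simulation the pipeline
recovers 39/40 planted sites with no false localizations.

A command-line front-end with `simulate`, `search`, `post`, `survey` and
`report` subcommands lives at `inst/cli/parlock.R`.

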