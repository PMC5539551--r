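---
title: "Screening low-biomass amplicon libraries against a background control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening low-biomass amplicon libraries against a background control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustscreen)
```

## The problem

Deep subseafloor sediments and basalts carry on the order of 10^3^–10^6^
cells cm^-3^ — so little DNA that amplicon libraries of a few thousand reads
can be dominated by exogenous sequences: seawater organisms entrained in
drilling fluids, skin and dust from handling, and the bacterial DNA resident
in extraction kits and PCR reagents. Without an explicit contamination
model, community profiles of such samples describe the laboratory as much as
the subsurface.

The screen implemented here assumes one additional sequenced library: a
**background control** — an artifact (e.g. a plastic bag recovered from a
core liner) that was exposed to drilling fluids, seawater, and every
handling step, but not to the sample interior. Its OTU inventory defines the
observable contaminant universe; everything else follows from comparing each
OTU's abundance in samples against that reference.

## The procedure

With counts `c[o,s]`, library sizes `N_s`, and relative abundances
`r[o,s] = c[o,s]/N_s`:

1. **Rare-OTU filter.** Drop OTUs whose pooled count over all libraries
   (control included) is below a minimum-abundance threshold — 5 reads, or
   equivalently 0.005% of total tags for datasets of ~10^5^ reads. Rare OTUs
   in pyrosequencing data are enriched in artifacts; the cost is that
   singleton-based richness estimators (Chao1 and kin) are invalid
   downstream, so the package never computes them.
2. **Four-bin classification.** Each surviving OTU goes to exactly one bin:
   `CONTROL_ONLY` (control, no samples), `SAMPLES_ONLY` (samples, no
   control), and for doubly present OTUs the ratio
   `R_o = max_s r[o,s] / r[o,control]` splits `TENFOLD_SAMPLE`
   (`R_o >= T`, default `T = 10`) from `CONTROL_SAMPLE` (`R_o < T`).
   Sample-enriched OTUs are interpreted as reagent contaminants that
   over-amplified in low-template reactions (or genuine residents carried
   into the control); comparable-abundance OTUs as seawater carry-over.
   Both are removed, as is the control column itself: only `SAMPLES_ONLY`
   reads feed community analysis.
3. **Sample exclusion.** A library is discarded entirely only on the
   conjunction of two independent signals: fluorescent tracer microspheres
   observed in the sample interior (physical evidence of drilling-fluid
   intrusion) and a control-overlap read fraction of at least 0.99
   (sequence evidence that essentially nothing sample-specific remains).
   Either signal alone yields a QC flag, not exclusion — microsphere-positive
   samples with mostly sample-specific reads are real data, and
   high-overlap samples without physical evidence may simply be very low
   biomass.
4. **Summaries.** Class/phylum composition (reads and fractions per taxon
   per sample), a shared-OTU abundance view (OTUs in ≥2 samples, ranked by
   total abundance, ties by OTU id), and the Jaccard presence/absence
   similarity matrix.

qPCR biomass estimates follow a parallel conservative logic: a target is
above detection only if *every* sample replicate exceeds *every*
extraction- and PCR-negative replicate by more than a factor of 2; the mean
of the higher negative-control type is subtracted from the sample mean;
below-detection results are carried as explicit records with the run's
limit of detection, never as zeros.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `rare_count_min` | 5 | reads (pooled) | standard minimum-abundance cutoff for 454-scale data |
| `rare_fraction` | 5e-5 | fraction of total tags | the same cutoff expressed proportionally |
| `ratio_threshold` (T) | 10 | — | sample:control relative-abundance ratio separating enrichment from carry-over |
| `ratio_comparison` | `ge` | — | an OTU exactly at T counts as enriched (the more inclusive screen); `gt` available |
| `sample_exclusion_overlap_threshold` | 0.99 | read fraction | exclusion demands near-total overlap, not mere majority |
| `detection_factor` | 2 | — | qPCR replicates must exceed negatives by more than this factor |
| `operons_per_cell` | 4 | operons cell⁻¹ | average bacterial rRNA operon copy number; set ~1–2 for Archaea |
| `sediment_density` | 2.5 | g cm⁻³ | converts per-gram copies to per-volume cells |

Two threshold comparisons are deliberately configurable because the
boundary conventions genuinely vary in practice: whether an OTU with exactly
5 pooled reads is kept (`rare_keep_at_threshold`, default keep) and whether
`R_o` exactly 10 is enriched (`ratio_comparison`, default yes). Defaults
take the more inclusive reading of each screen; both switches are surfaced
rather than silently resolved.

## The synthetic world

`generate_dataset()` draws each sample library multinomially from

```
(1 − φ_s) · endemic(material_s)  +  φ_s · (ω · seawater + (1 − ω) · reagent)
```

with contaminant fraction `φ_s = κ/(κ + B_s)` — the simplest monotone map
reproducing the empirical pattern that low-biomass libraries carry
proportionally more contamination. The control library is drawn from the
contaminant pool, optionally with a leak `ε` of pooled endemic reads
(sample material carried into the control during handling). Source pools
are lognormal rank-abundance communities (σ = 1.5) with field-plausible
lineage labels (endemic: Chloroflexi/Atribacteria/Aerophobetes and kin;
seawater: SAR11/SAR86/Flavobacteriia; reagent: *Arthrobacter*,
*Rhodococcus*, Firmicutes). Default sample biomasses span ~3.5 orders of
magnitude so φ covers roughly 2–98%, library sizes are drawn uniformly
from 3,000–16,000 reads, and the control has 3,732 reads — the scale of a
single 454 run on this sample type. A `shared_fraction` option plants a
subset of seawater OTUs in the endemic profiles to emulate genuinely
cosmopolitan taxa.

What the generator does **not** emulate: read-level error (quality,
chimeras, homopolymers), PCR primer bias, phylogenetic structure among
OTUs, and spatial covariance among samples. A green test therefore
establishes that the screening *arithmetic and bookkeeping* are correct
under the stated mixture model — not that the screen recovers truth for
any real community.

## What recovery can and cannot reach

With `ε = 0` the endemic and contaminant supports are disjoint, so an
endemic OTU can never appear in the control: **specificity is exactly 1 by
construction**, and the suite asserts equality, not approximation.
Sensitivity is different: the screen can only remove a contaminant OTU that
the control *caught*. A contaminant OTU with ≥5 pooled reads in the samples
but zero reads in the 3,732-read control is classified `SAMPLES_ONLY` — by
the bin definitions, correctly so. Measured across seeds at the default
world, sensitivity is 0.91–0.99, and the suite asserts the exact identity

```
sensitivity = fraction of contaminant OTUs with nonzero control count
```

rather than pretending to 1.0. The perfect-recovery case (sensitivity =
specificity = 1.0, zero contaminant reads retained) is asserted in the
world where it is guaranteed: disjoint supports with φ ≈ 0, where the
control is the only contaminant source. This is the method's structural
limit worth remembering when interpreting real screens: a deeper control
library buys sensitivity.

A related property one might conjecture — that the control leak `ε`
improves sensitivity — does not hold in this model: `ε` moves *endemic*
reads into the control, which only dilutes its coverage of contaminant
OTUs (measured effect across seeds: flat to slightly negative). What `ε`
actually costs is specificity, since leaked endemic OTUs become
`CONTROL_SAMPLE` and are wrongly removed; the conservative screen knowingly
accepts this trade.

## Numerical and degenerate-input choices

* Normalization is plain division by `N_s` — deterministic, and equivalent
  in expectation to rarefying to a common depth without its sampling noise.
  No rarefaction mode is provided.
* No pseudocounts anywhere: presence is `count > 0`, and an OTU absent
  from the control is `SAMPLES_ONLY` regardless of how abundant it is in
  samples.
* A zero-read sample column is an error naming the sample (its relative
  abundances are undefined); an all-zero OTU row is likewise an error at
  binning (it belongs to no bin).
* Jaccard for two empty OTU sets is defined as 0 with a warning (the union
  is empty); an empty sample's diagonal is 0, not 1.
* The corrected qPCR copy number is floored at 0; below-detection panels
  refuse to produce a number at all.
* Filtering removes every OTU → warning plus a structurally valid empty
  table, not an error; report files are emitted header-only.
* All output tables are sorted (OTU id, then sample id) so identical inputs
  produce byte-identical files.
* Libraries with no sequenced control (e.g. archaeal primer sets that
  recover nothing from the control) run as an explicit unscreened
  pass-through (`allow_no_control = TRUE`), never as a silent screen
  against an absent reference.

## The cell-density formula

`cells_per_cm3()` implements the stated conversion
`copies g⁻¹ × ρ / n_op` literally. Published converted ranges for this
sample type are sometimes reproducible only as `copies g⁻¹ × ρ` — i.e.
with the operon division omitted (a factor-of-4 discrepancy). The package
follows the formula, exposes `operons_per_cell` so either convention is
one argument away, and treats no printed converted value as a test oracle;
the formula itself is verified by direct arithmetic cases.

## Known limitations

* The screen is presence-based at its core; it cannot separate a genuine
  resident that also lives in seawater from carry-over (such OTUs are
  removed — the conservative direction for contamination, the lossy one
  for ecology; a few percent of genuinely shared taxa are the price).
* Sensitivity is bounded by control sequencing depth (above).
* One control per run; multiple controls must be merged upstream or run
  separately.
* No statistical decontamination (frequency/prevalence mixture models);
  those are alternative methods, not implemented here.
* Richness estimation is deliberately unsupported post-filter.
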