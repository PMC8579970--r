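---
title: "Detecting biofilm dispersal from effluent community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biofilm dispersal from effluent community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sulfate-reducing bacteria (SRB) respire sulfate to hydrogen sulfide. In
water-flooded oil reservoirs and similar engineered systems, SRB biofilms
drive "souring" — H2S accumulation with serious safety, corrosion and cost
consequences. Nitrate dosing is the standard countermeasure: it feeds
heterotrophic nitrate reducers that outcompete SRB for electron donors and
stimulates nitrite production that inhibits dissimilatory sulfite
reductase. The catch is that the sessile (biofilm) community, the real
reservoir of sulfidogenesis, cannot be sampled in the field; only the
planktonic (effluent) community can.

`soursentinel` implements a detection procedure built on one observation:
when nitrate treatment succeeds in disrupting an SRB biofilm, biofilm
members slough into the effluent. A short-lived surge of a *specific SRB
population* (SSP) in the effluent, a few days after nitrate dosing starts,
is therefore an indirect read-out of biofilm disruption. The package turns
that observation into a reproducible pipeline:

1. **Phase segmentation.** Each (column, time point) is labelled
   sulfidogenesis (S), transition-to-mitigation (TM), mitigation (M) or
   rebound (R) from the sulfide series and the nitrate schedule. TM is the
   window after nitrate initiation while sulfide is still strictly above a
   threshold (default 1 mM); the first treated point at or below the
   threshold enters M, and M is not revoked by later blips — the observed
   transition windows are contiguous. Points after nitrate withdrawal are
   R.
2. **Abundance bookkeeping.** Read counts are divided by 16S rRNA gene
   copy number, summed over the sequence variants assigned to the same
   closest-genome label, and expressed as percent per sample.
3. **SSP selection.** Within a treated column, SRB-flagged genomes are
   ranked by their TM-phase mean relative abundance. The ranked list, not
   a single hard call, is reported: real columns can carry two surging SRB
   populations at once.
4. **Anomaly statistic.** For a signal $x_t$ (SSP or DSR-pathway relative
   abundance) the anomaly is $a_t = (x_t - \bar{x}) / \bar{x}$, with
   $\bar{x}$ the mean over the column's own observed effluent series.
   Anomalies sum to zero over the window by construction.
5. **Critical time points.** TM-phase points whose SSP relative abundance
   strictly exceeds the TM-phase mean. Ties are not critical — a
   conservative reading of "higher than the average".
6. **Absolute abundance.** SSP cells/ml = (relative abundance %)/100 ×
   flow-cytometry total cell count, after Tukey-fence outlier removal
   (fences at Q1 − 1.5 IQR and Q3 + 1.5 IQR) applied per column and phase.
7. **Pathway corroboration.** The predicted dissimilatory sulfate
   reduction (DSR) pathway share — the summed relative abundance of
   genomes annotated as carrying the pathway — gets the same anomaly
   treatment; the cross-column average anomaly and a penalized-spline
   (GAM) trend with a ±2 SE band summarise it.

Rank tests (Wilcoxon, Kruskal-Wallis) are computed and reported
descriptively throughout; no pipeline decision gates on a p-value.

## The synthetic experiment generator

The raw sequence data behind the emulated study design are not shipped
with the package, so every downstream stage is validated against a
generator with known ground truth. Its defaults are the study conditions:
20 columns (10 nitrate-treated), 148 days, nitrate from day 43 to day
115, sequencing depth drawn from a normal with mean 40,709 and SD 10,527
(truncated at 1,000 and rounded), 19 columns sacrificed at one of four
harvest days (68, 73, 113, 148) yielding 57 sessile samples from three
column sections each, and a dispersal pulse 2 and 4 days after nitrate
initiation.

Per column, a base genome composition is drawn (gamma-normalised, i.e.
Dirichlet-like), with SRB genomes holding 3% of the effluent community
during sulfidogenesis and a nitrate-responsive "bloom" genome that
expands under treatment. Latent compositions get per-(taxon, day)
lognormal jitter (sdlog 0.3) — the right-skewed overdispersion typical of
community time series — and are renormalised. Reads are multinomial at
the drawn depth with probabilities weighted by 16S copy number, so the
latent fractions are *cell* fractions and the pipeline's copy-number
correction is doing real work when it recovers them.

The dispersal pulse is modelled as additive mixing of the column's
sessile composition (SSP fraction 0.45 by default — a free parameter, as
sessile composition is not quantified in the emulated design) into the
effluent, with the mixing weight solved *after* jitter so that the SSP's
latent fraction at a dispersal day equals exactly `dispersal_fold` times
its realised pre-injection TM mean. `dispersal_fold = 1` disables the
injection and yields a negative-control experiment. The default fold of 8
represents the "sudden increase" regime the detector is meant for.

Sulfide follows a saturating rise to a 4 mM plateau; in treated columns
an exponential decay starts 6 days after nitrate initiation (the lag
guarantees a real TM window above 1 mM containing the dispersal days) and
a rebound rise follows nitrate withdrawal. Gaussian measurement noise
(SD 0.05 mM) is truncated at zero. Ground truth records the noise-free
phase boundaries; with the noise set to 0, `assign_phases()` recovers
them exactly.

Total cell counts are lognormal (median 1e7 cells/ml, sdlog 0.4); with
probability 0.02 a count is multiplied by 100 to emulate the gross
outliers that flow cytometry occasionally produces, which the Tukey
flagging is expected to remove.

What the generator does *not* emulate: sequence-level error, chimeras,
archaea, compositional covariance between taxa beyond the shared
renormalisation, temperature effects, and any geochemistry beyond the
phenomenological sulfide curve. Passing recovery tests therefore show the
statistical machinery is sound under realistic noise and depth — not that
the biological signal in any particular field system will be as clean.

## Numerical and design choices

- **Time** is integer day offsets from experiment start; calendar dates
  in input files are converted on load against the earliest date present.
- **Quartiles** use linear interpolation at positions $1 + (n-1)q$
  (R's default type-7 convention); the convention is fixed because Tukey
  fences are otherwise not reproducible across software. With fewer than
  4 values nothing is flagged.
- **Shannon** is reported in nats and **Simpson** as the Gini-Simpson
  complement $1 - \sum p_i^2$, matching the conventions of the ecology
  tooling this package follows; both are configurable (`base`,
  `variant = "dominance"`).
- **PCoA** retains only positive-eigenvalue axes and reports each axis's
  share of the positive-eigenvalue sum; ordination runs on relative
  abundances (%).
- **The anomaly window** is the column's own observed effluent series,
  whatever phases it spans — columns sacrificed early simply have shorter
  windows. Sessile samples are never part of the window.
- **DSR normalisation** is community-based: the summed relative
  abundance of DSR-positive genomes over the whole community. Pathway
  presence is binary; no attempt is made to model within-genome pathway
  dosage.
- **The GAM smoother** uses a cubic regression spline basis with
  dimension `min(10, n/4)` (bounded below at 4) and smoothness chosen by
  generalized cross-validation; the reported band is the fit ±2 standard
  errors. At least 5 distinct time points are required.
- **Missing sulfide** at a requested time point is carried forward from
  the last observation; a point before the first observation is an error
  rather than a guess.
- **Per-column thresholds** are supported (a named vector), because
  printed transition windows in the emulated design imply one column used
  0.94 mM instead of 1 mM; the default is 1 mM everywhere.
- **Tie-breaks** in SSP ranking are lexicographic by genome label, so
  reports are deterministic.
- **Randomness**: one master seed; per-column substreams are derived from
  it, so any column can be regenerated independently and
  `generate_experiment()` is byte-reproducible.

## Validation scale

The packaged test-and-acceptance suite runs the full study-scale
configuration (20 columns, ~840 samples, ~50 taxa) across 20 generator
seeds for the recovery experiments — about 850 pipeline-days of synthetic
data per run — and checks: dispersal-day sensitivity ≥ 0.9 with the
rank-1 SSP matching truth in ≥ 9/10 treated columns per run; SSP cell
abundance at critical time points exceeding the S/M/R phase medians in
≥ 8/10 columns per run; and the cross-column average DSR anomaly peaking
on an injected dispersal day after treatment in ≥ 80% of runs for treated
columns, with no such alignment in nontreated columns. Negative-control
runs (`dispersal_fold = 1`) verify that above-mean TM points occur at a
rate well below the detector's sensitivity — the criterion flags
above-mean points by construction, so its false-positive rate is bounded
near one half, not zero; critical time points are a *screen* to be read
alongside the cell-abundance and DSR corroboration, not a test with a
controlled error rate.

## Known limitations

- The SSP selection rule (TM-mean ranking of SRB genomes) is a
  reconstruction: the emulated study describes its outcome, not its
  algorithm. The ranked multi-candidate output is deliberately
  conservative.
- Bacteria only; systems where sulfidogenic archaea matter need an
  extended annotation model.
- The anomaly statistic divides by the column mean, so signals absent (or
  nearly absent) from a column are rejected rather than scored.
- Constrained ordination (CAP) and raw-read processing (denoising,
  phylogenetic placement, pathway inference) are out of scope; the
  pipeline consumes already-annotated count tables.
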