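---
title: "Single-base m6Am site calling from four-library enrichment sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-base m6Am site calling from four-library enrichment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its logic

N6,2'-O-dimethyladenosine (m6Am) occurs at the first transcribed nucleotide
of many mRNAs, immediately adjacent to the m7G cap. The anti-m6A antibody
used in MeRIP-style experiments cannot distinguish m6Am from internal m6A, so
m6Am-Seq resolves the ambiguity experimentally with four libraries prepared
from the same fragmented RNA:

* **input** — no enrichment; the background fragment distribution;
* **m7G-IP** — anti-m7G pulldown; enriches cap-retaining fragments;
* **FTO− m6A-IP** — anti-m6A pulldown of untreated RNA; enriches fragments
  carrying either mark;
* **FTO+ m6A-IP** — anti-m6A pulldown after in-vitro FTO demethylation, which
  removes m6Am efficiently while leaving internal m6A essentially intact.

A genuine cap m6Am signal is therefore (i) enriched in the FTO− IP over
input, (ii) depleted in the FTO+ arm relative to FTO−, (iii) located at the
transcript 5′ end, and (iv) m7G-positive. Internal m6A satisfies (i) but
fails (ii)–(iv).

Within a candidate peak, every adenosine is scored with two per-nucleotide
statistics computed from the tracks:

* `m1 = (FTO− start reads) / (FTO− depth)` — the *cap signature*. A fragment
  can only carry the cap mark if it retains the 5′ end, and such fragments
  start exactly at the modified base, so a true cap site is a dominant
  fragment start.
* `m2 = (FTO− depth − FTO+ depth) / (FTO− depth)` — the *demethylation
  sensitivity*, computed on cpm-normalized depths and clamped to [0, 1].

The combined score is `m1 × m2` by default. The product is the minimal rule
that is high only when a position is simultaneously a dominant start and
FTO-sensitive; because the exact combination rule used in the original
analyses is not recoverable, `min` and `mean` combiners are also provided
(`combine=` argument) and the choice is surfaced prominently rather than
hidden. `m1` uses raw FTO− counts (a within-library ratio is scale-free);
`m2` uses cpm so the two FTO arms are comparable despite different library
sizes.

## Pipeline stages and their tunables

| stage | parameter | default | meaning |
|---|---|---|---|
| peak scan | `window` / `step` | 25 / 5 nt | sliding-window size and stride |
| peak scan | `min_fold` | 2 | (IP cpm + pc)/(input cpm + pc) threshold |
| peak scan | `min_ip_depth` | 5 | mean raw IP depth floor per window |
| peak scan | `pseudocount` | 0.5 cpm | symmetric stabiliser for folds |
| FTO filter | `min_depletion` | 0.3 | minimum 1 − FTO+/FTO− depth ratio |
| cap filter | `max_tss_distance` | 100 nt | maximal summit distance from 5′ end |
| cap filter | `m7g_min_fold` | 2 | m7G-IP/input fold inside the peak |
| site call | `min_site_depth` | 10 | raw FTO− depth floor at a position |
| site call | `min_score` | 0.1 | combined-score threshold |
| site call | `context_width` | 30 nt | site-centred context, N-padded |
| TE | `log2_threshold` | 1 | symmetric UP/DOWN boundary on log2 TR |

The qualitative description of peak calling ("highly enriched", "decreased
after FTO") pins down no numeric thresholds; the defaults above are
conventional MeRIP-style values and every one of them is exposed in the run
configuration. Fold changes are always computed on cpm-normalized depth with
a symmetric pseudocount so library-size differences cannot masquerade as
enrichment, and `fto_depletion` is clamped at 0 when sampling noise makes the
FTO+ mean exceed the FTO− mean. Overlapping or abutting enriched windows are
merged before the summit (position of maximal FTO− IP normalized depth, ties
broken toward the smaller coordinate) and the enrichment are recomputed on
the merged interval, which makes peak merging idempotent.

Translation efficiency is `TE = (footprint CDS cpm + pc)/(RNA cpm + pc)` per
gene and the translation ratio is `TR = TE_condition / TE_control`; a gene is
TE-downregulated when `log2(TR) ≤ −1` — the conventional reading of a
"1-fold decrease", i.e. halving, with an inclusive boundary — and
TE-upregulated symmetrically at `log2(TR) ≥ +1`. The symmetric UP rule is an
assumption: only the DOWN rule is pinned by the assay description.
Integration across replicates and assays is done at gene level: a gene
counts once however many sites it carries, shared genes are the intersection
across samples, and the reported fraction is |shared ∩ TE-changed| / |shared|
to one decimal place.

## What the simulator emulates

`simulate_transcriptome()` draws 250–500 nt transcript models (5′UTR/CDS/
3′UTR boundaries included), plants cap m6Am on an A at the transcription
start and internal m6A in a planted `GGACT` (DRACH-like) context at least
150 nt downstream of the 5′ end, and records every site in a truth table
with its stoichiometry (default 0.8). `simulate_libraries()` then draws
fragments (truncated-normal lengths, mean 30, sd 5, minimum 20 nt), assigns
per-molecule methylation as Bernoulli(stoichiometry), erases marks in the
FTO+ aliquot with probability 0.9 (m6Am) or 0.05 (m6A) *before* IP, and
applies IP selection by rejection sampling with acceptance weight
`ip_enrichment` (default 5) for antibody-reactive fragments.

Two modelling choices matter and are deliberate:

* **Fragmentation-aware starts.** Random fragmentation of an intact molecule
  yields exactly one cap-retaining fragment per molecule, so the probability
  that a sampled fragment starts at the 5′ end is ≈ fragment length /
  transcript length (about 1/10 here), not 1/(transcript length). Sampling
  starts uniformly over all positions would under-represent capped fragments
  by more than an order of magnitude and provably caps the achievable
  window-mean IP/input fold at the cap near 1.25 — below any sensible peak
  threshold — regardless of sequencing depth. The simulator therefore draws
  "capped" with probability 1/m (m = round(effective length / mean fragment
  length)) and places interior starts uniformly otherwise.
* **The molecule 5′ end coincides with the cap site.** By default cap sites
  sit at transcript position 0. With `cap_window > 0` the site — and with it
  the molecule 5′ end, modelling alternative transcription starts within an
  annotated model — is placed up to that many nt downstream, which also
  places the upstream C of the "CA" cap context on the transcript so motif
  recovery can be exercised.

Depths default to 2×10^5 fragments per library over 200 transcripts, which
puts per-position coverage near 100× and runs a full four-library experiment
in a few seconds; the validation suites aggregate 10–20 independent seeds at
these sizes. All randomness flows from the single seed in `sim_params()`
(the library sampler derives its stream from seed + 1 so transcriptome and
libraries are independently reproducible).

What the simulator does **not** model: genome coordinates and splicing,
sequencing errors and quality scores, antibody off-target binding, duplicate
fragments, multi-mapping, or positional coverage biases other than the cap
effect. Passing the simulation checks therefore demonstrates that the
statistics and filters behave as designed under the assay's idealised
assumptions — not that real libraries, with their messier backgrounds, would
yield the same recall.

## The synthetic Ribo-Seq block and a cpm caveat

`simulate_te_counts()` draws lognormal baseline expression, applies known
per-gene log2 TRs, and samples multinomial counts (default 25 genes, five
per log2 TR class in {−2, −1, 0, 1, 2}, 10^6 counts per table; this keeps
per-gene counts high enough that Poisson noise on log2 TR stays well under
0.1). Because TE and TR are built from cpm, a *net* shift in translational
output is absorbed by the renormalization and would bias every recovered TR
by a constant — the same composition effect that motivates TMM-style
corrections in differential expression. The generator therefore conserves
total footprint mass between conditions by default (`balance_mass = TRUE`),
rescaling the baseline expression of down-shifted genes to offset the
up-shifted ones; with a one-sided shift (as in the demo pipeline, where only
modified genes change) the recovered ratios are attenuated by the
composition factor, which is why the demo plants a log2 shift of 2 to clear
the ±1 classification boundary. This is a genuine limitation of cpm-based
TE, not of the estimator.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere; a "start read" is a fragment's
5′-most transcript position. Zero-depth positions score m1 = m2 = 0 rather
than NaN; a zero FTO− mean makes a peak's depletion 0; transcripts shorter
than the window are scanned as a single window; empty alignment sets yield
empty (not missing) tracks, peak lists and site tables; an empty site list
gives an empty motif sentinel rather than an error; contexts at transcript
edges are N-padded and all-N PFM columns are reported as NA with consensus
"N". Count tables with a zero total are a hard error (cpm undefined), as are
records outside transcript bounds (reported with the offending record) and
start counts exceeding depth.

## Known limitations

* The combined site score is a design choice, not a measured constant;
  conclusions that depend on its exact functional form should be checked
  against the `min` and `mean` variants.
* The m7G arm is used only as a peak-level fold filter; no attempt is made
  to deconvolve cap heterogeneity.
* There is no significance model for peaks or sites (none is defined for the
  assay); thresholds are operating points, and the modification-free
  simulation provides the corresponding empirical false-positive control.
* Gene-level integration assumes one transcript per gene in the simulator;
  real annotations with multiple isoforms per gene would require collapsing
  site calls before intersection.
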