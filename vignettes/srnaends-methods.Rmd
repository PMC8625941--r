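---
title: "Methods: differential RNA end mapping and sRNA maturation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential RNA end mapping and sRNA maturation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many bacterial small regulatory RNAs are not transcribed from their own
promoters but are carved out of the untranslated regions (UTRs) of mRNAs by
ribonucleases. Whether a given sRNA end was made by transcription initiation,
intrinsic termination, endonucleolytic cleavage (RNase E, RNase III) or
exonucleolytic pausing (PNPase) can be read out genomically: an end that is
generated by an enzyme is abundant in wild-type RNA-seq end libraries and
depleted when that enzyme is inactivated. `srnaends` implements this whole
inference chain as composable, tested stages:

1. **End-count tracks** (`count_read_ends()`, `read_bedgraph()`): per-position
   counts of read 5' and 3' ends, per replicon, strand and end type, with the
   per-sample library size (counted reads) attached for CPM normalization.
2. **Differential end calling** (`call_differential_ends()`): positions whose
   5'- or 3'-end abundance differs between wild type and an enzyme mutant at
   the published operating point — `|log2FC| >= 1` with Benjamini–Hochberg
   adjusted `p <= 0.05`, the adjustment taken genome-wide across both end
   types of one comparison.
3. **Origin classification** (`classify_origin()`): strand-matched overlap
   (>= 1 nt) of each sRNA with predicted 5'/3' UTRs and gene bodies, giving
   the classes `five_prime_utr`, `three_prime_utr`, `orphan`, `unclassified`.
4. **Mechanism assignment** (`assign_end_mechanisms()`): every TSS,
   terminator or wild-type-enriched differential end whose anchor falls
   within ±5 nt of an sRNA end (±10 nt for terminators) is a potential
   generation mechanism; all co-occurring features are kept; ends with no
   feature are `unknown`.
5. **Processing quantification** (`probe_fold_changes()`, `ratio_table()`,
   `students_t_two_sided()`, `trend_agreement()`): densitometry and reporter
   tables become loading-normalized abundances, mature/precursor ratios,
   log2 fold changes, ±0.65 trend classes and trend-agreement matrices.

Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) and
BED/bedGraph (0-based half-open) are converted at the I/O boundary, which
keeps the ±window arithmetic unambiguous. sRNA ends are single nucleotides —
the first and last transcribed base — so windows are point-centred intervals
with inclusive bounds ("−5 nt to +5 nt" spans 11 positions).

## The differential-end statistic

The published pipelines report the thresholds (fold change, adjusted p) but
not the per-position test, so the statistic is this package's own, explicit
choice. Candidate positions are those whose summed raw count reaches
`min_count` (default 10) in at least one group. That selection rule has a
statistical consequence that drove the design: candidates are *selected for
imbalance* between the groups, so any well-calibrated unconditional test —
a moderated t in particular — assigns small p-values to background positions
that were only selected because one group's Poisson noise happened to spike,
and the realized false-discovery proportion collapses. Two statistics are
offered:

* `stat = "exact_poisson"` (default): an exact two-sided binomial test of
  the pooled wild-type raw count against the proportion expected from the
  summed library sizes, **conditioned on the selection region**
  (`x >= min_count` or `total − x >= min_count`). Conditioning restores
  calibration for the tested (selected) positions under Poisson sampling,
  and the test is essentially exhaustive for true ends, where pooled counts
  differ by orders of magnitude. Measured under the generator's study
  conditions (signal depth 100, background 1, residual 0.05, n = 3): the
  caller recovers all implanted ends with false-discovery proportion below
  0.05, and emits nothing under the null (residual 1).
* `stat = "welch"`: a two-sided Welch t-test on `log2(CPM + pseudocount)`
  across replicates. Its per-position variance term makes it robust to
  overdispersion beyond Poisson, at a real cost in power with triplicates
  (about 90% sensitivity under the same conditions). This is also the
  statistic of the single-position surface `test_position()`, which falls
  back to the (unconditional) exact binomial when a group has a single
  replicate.

The log2 fold change is always
`log2((mean_wt_CPM + pc) / (mean_mut_CPM + pc))` with `pc = 0.5`, oriented
wild type over mutant so that enzyme-generated ends are positive
(`wt_enriched`). Mechanism assignment consumes only `wt_enriched` records by
default; mutant-enriched records usually mark accumulating precursors, not
generation sites, and can be included with `diff_direction = "both"`.
Benjamini–Hochberg is implemented in the package (step-up with cumulative
minimum, capped at 1) and is cross-checked against `stats::p.adjust` in the
test suite.

## Origin and mechanism conventions

* Overlap semantics follow BEDtools `window` with `-s`: 1 nt of same-strand
  overlap suffices. An sRNA overlapping both UTR kinds, or only a gene body,
  is `unclassified` — the class for sRNAs that cannot be assigned a distinct
  origin; the rule is configurable in the sense that it is a plain, small
  function with documented behaviour.
* TSS are eligible only for 5' ends and terminators only for 3' ends
  (biological identifiability); `gate_ends = FALSE` reproduces a naive
  windowed overlap. Differential ends always match the sRNA end of the same
  end type.
* Terminator features are anchored at the 3'-most base of the annotated
  terminator interval on its strand; no anchor convention is universal, and
  this one puts the anchor at the base the terminator actually defines.
* Ties and multiplicities are kept: if a TSS and an RNase E end both fall in
  a window, both are reported, and summaries count incidences per
  (origin × end × mechanism) cell.

## Quantification conventions

* Signals are normalized to the 5S rRNA loading control of the same lane;
  in mature/precursor ratios the control cancels algebraically, and the test
  suite asserts that identity numerically.
* Trend classes use strict inequalities: `log2FC > 0.65` increased,
  `< −0.65` decreased, boundaries inclusive to `no_change`.
* Fold changes are ratios of group means (triplicate means in the emulated
  design); a paired mode averages per-lane log ratios for same-membrane
  comparisons.
* The t-test is the classical pooled-variance Student's t
  (`df = n_a + n_b − 2`), per the stated test; Welch remains available for
  the end-calling module where variances genuinely differ. Zero pooled
  variance with equal means returns `p = 1` by convention. Ratio tests use
  raw ratios by default with a log-ratio option, since the original scale is
  not documented.
* Replicates with a non-positive precursor signal are flagged unquantifiable
  (`NA` with a warning), not silently dropped.

## What the synthetic generator emulates

`simulate_annotation()` + `simulate_end_tracks()` +
`simulate_signal_table()` generate every input with known ground truth. The
defaults are the study conditions, chosen once:

* 79 sRNAs (the master-set size) in origin proportions 38 : 14 : 16
  (orphan : 5'UTR : 3'UTR) over the three placeable classes — the published
  proportions among assignable sRNAs. The `unclassified` class arises from
  ambiguous overlap and is not constructed deliberately.
* biological triplicates (`n_replicates = 3`), Poisson counts with
  `signal_depth = 100` at true ends over `background_rate = 1` everywhere,
  and `mutant_residual = 0.05` at enzyme-dependent ends in the cognate
  mutant only.
* mechanism probabilities echo the observed picture: 5' ends dominated by
  TSS with a substantial RNase E contribution; 3' ends split between
  terminators, PNPase pausing, cleavage and `unknown`.
* `multi_prob` (default 0.1) implants a second, distinct mechanism at an end
  so that the multi-assignment path is exercised; `terminator_jitter`
  (default 0) can displace terminator anchors within the ±10 nt window.
* one RNG stream per (strain, replicate), derived from the master seed by
  fixed offsets, so identical configurations yield byte-identical files and
  partial re-runs reproduce exactly.

What it deliberately does **not** model: read-level artefacts (mapping
ambiguity, soft clipping, rRNA contamination), overdispersion beyond Poisson
(available as a gamma-mixing option but off by default), precursor-end
accumulation in mutants, transcription-unit structure beyond one gene per
locus, and sequence content entirely. Passing the recovery tests therefore
shows that the inference chain is correct under its stated sampling model,
not that real libraries meet that model; the Welch option and the
overdispersion knob exist precisely to probe departures.

## Problem sizes and numerical choices

The test suite and the acceptance script run the recovery analyses at
75–79 sRNAs on 42–50 kb replicons (~50 implanted ends per enzyme, ~160k
background track cells per group), sizes at which every property is measured
on thousands of positions while a full run stays in minutes on one CPU. Exact
binomial tails are computed by summing `dbinom` over the (truncated) support;
fold changes use a 0.5 pseudocount on the CPM scale; BH ties are handled by
the cumulative-minimum step-up form. Degenerate inputs are defined, not
accidental: empty GFF3 files parse to empty record sets, empty bedGraphs to
empty tracks, identical groups give `log2FC = 0, p = 1`, and an empty
candidate set gives an empty call table.

## Known limitations

* The per-position test treats positions independently; adjacent-position
  peaks are not clustered (by design — the published analysis operates on
  single positions).
* With a single replicate per group, only the pooled count test is
  available, and it is exactly calibrated only under Poisson sampling.
* Origin classification takes the UTR and gene annotations as given; no
  attempt is made to re-predict UTRs, TSS or terminators.
* The `unclassified` rule is one defensible reading of "could not be
  assigned a distinct origin"; alternative readings (e.g. nearest-feature
  tie-breaks) would change borderline cases and can be emulated by filtering
  the inputs.
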