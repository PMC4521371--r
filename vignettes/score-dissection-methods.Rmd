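---
title: "Dissecting profile-HMM alignment scores: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting profile-HMM alignment scores: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmdissect)
```

## The problem and the model

Profile-HMM searches score a whole sequence-to-domain alignment. That score
mixes two very different kinds of evidence: similarity over the
*fold-critical* columns (the secondary-structural elements that define the
domain fold, hence the part of the alignment that actually carries the
homology signal) and similarity over the *remnant* columns (loops, linkers,
low-complexity and disordered stretches). Conserved remnant stretches can
make a spurious hit look statistically significant, and divergent remnant
stretches can sink a genuinely fold-related hit below the reporting
threshold.

This package re-evaluates hits *after* the search, with no change to the
aligner:

1. the full alignment bit score is **reconstructed** from the model's
   emission, transition and invariant log-odds terms along the reported
   path;
2. the score is **dissected** into a fold-critical sum and a remnant sum
   using a per-model-column mask;
3. each sum is pushed separately through the model's extreme-value
   statistics, giving an *original*, a *fold-critical* and a *remnant*
   E-value, plus the **ratio measure**
   `log10(E_fold-critical / E_remnant)` (low means the fold carries the
   significance);
4. hits are classified TP/FP/TN/FN from the original and fold-critical
   E-values; the FN class — insignificant overall but fold-critical-significant —
   is the rescued class, and only TP/FN hits go forward;
5. overlapping glocal (H2-style) and local (H3-style) hits for the same
   model are paired at overlap ratio >= 0.9 and combined into an
   **error-adjusted domain coverage**
   `coverage = 1/2[(1 - fpr_H2) cov_H2 + (1 - fpr_H3) cov_H3]`, where each
   `fpr` is the empirical false-positive rate of the hit's measure in a
   negative-hit calibration table;
6. the two coverage scores (ratio-based and fold-critical-E-based) are
   mapped through benchmark ROC tables to FPRs whose sum — the **total
   FPR**, in [0, 2] — is the ascending ranking key for reported hits.

## Score reconstruction and the crediting rules

All scores are held in bits. A path record contributes its emission (match
and insert states) plus the transition entering its state. Class crediting:
match and delete records take their own column's mask label; insert records
take the label of the match column they follow (inserts live *between*
columns, and attaching them to the preceding column keeps the rule local
and deterministic). The position-independent terms — entry `B->M_k`, exit
`M_k->E`, and any model-level invariant — are credited to the fold-critical
sum: they are normalisers needed for any EVD evaluation, and placing them
in one documented, configurable place keeps `fc + rem = full` exact (the
additivity is asserted to 1e-6 bits in the tests, and holds to machine
precision).

The two dialects keep their own statistics: glocal hits are evaluated
against a Gumbel (location `mu`, scale `lambda`, E =
`z (1 - exp(-exp(-lambda (x - mu))))`), local hits against the
forward-score exponential tail (E = `z min(1, exp(-lambda (x - tau)))`).
Bias/composition corrections are *not* applied to dissected sums: they are
defined on whole alignments and cannot be reconstructed for a partial sum.
E-values are computed in log space; below 1e-300 they are reported as exact
zero, which triggers the rule that hits with a zero remnant E-value are
excluded from ratio-based calibration (their ratio would be infinite).
Below the location parameter the Gumbel survival saturates at `z` in double
precision; strict monotonicity of E in the score therefore holds over the
representable range, which is the range that matters for any threshold
decision.

One classification cell is not pinned down by the published criteria: an
original-significant hit whose fold-critical *and* remnant sums are both
insignificant. We label it FP — its significance is not fold-supported, and
it is discarded either way since only TP/FN hits are retained.

## Column masks

DSSP-derived masks treat codes H, E, I, T and S as fold-critical and the
gap codes (`-`, `?`) as remnant. Codes outside both sets (G, B, C, ...) are
remnant by elimination under the default policy, with a one-time warning
per code, because the enumerated fold set may or may not have deliberately
excluded the 3-10 helix and isolated bridge; the policy is an argument.
Remnant runs shorter than 10 columns are folded back into the globular
segments — short non-globular stretches are generally well conserved and
belong to the fold for scoring purposes. The merge is idempotent.

Predictor-derived masks combine four per-column scores in [0, 1] — sequence
conservation (quality score), secondary-structure prediction, low
complexity (SEG-style two-threshold entropy segmentation; window 25,
trigger 3.1 bits, extension 3.4 bits) and globularity (GlobPlot-style
smoothed running-sum propensity; smoothing 10, domain join 10, domain peak
40, disorder join 4, disorder peak 5) — as a weighted sum with weights
0.61, 0.50, 0.41 and 0.39 (each predictor's best benchmark TPR-FPR
margin). The weighted score is min-max normalised per model and thresholded
at 0.5, ties declared fold-critical. A constant weighted vector carries no
information: it is normalised to 0.5 everywhere with a warning, leaving the
decision to the tie rule. Alignments with fewer than 5 sequences fall back
to the conservation score alone; the structure/complexity/globularity
predictors are unreliable on very shallow alignments.

Two upstream formulas are not published in a reproducible form and are
therefore package-defined contracts with an escape hatch (an externally
supplied score vector is accepted anywhere a predictor vector is):

* **quality score** — per-pair BLOSUM62 similarity normalised between the
  matrix minimum and the smaller of the two diagonal entries, averaged over
  pairs and multiplied by the non-gap fraction; identical gap-free columns
  score exactly 1.
* **per-column aggregation** of per-residue predictor labels — the
  structured fraction over non-gap residues, which matches the stated
  [0, 1] score range and the sequence-count floor.

The bundled disorder-propensity table is a documented approximation in the
style of the Russell/Linding scale (order-promoting residues negative,
disorder-promoting positive); every consumer accepts a replacement vector.

## Calibration

Empirical FPR tables are histograms of negative-hit measures (log10) on a
unit grid from -205 to 3; the lookup is the cumulative frequency through
the bin containing the cutoff, with edge values belonging to the lower bin
(`P(measure <= x)` semantics). Negative hits are those whose model is not
in the query superfamily's mapped set, after an original-E <= 20 candidate
listing.

The packaged anchor tables reconstruct the published calibration from its
printed anchor points — fold-critical E-value: FPR 0.10 at 10^-3.45 and
0.01 at 10^-6 (glocal), 0.10 at 10^-6 and 0.01 at 10^-9 (local); ratio:
0.10 at 10^-2.25 (glocal) and 10^-9.1 (local) — by log-linear interpolation
between anchors, pinned monotone to 0 and 1 at the grid limits. The grid is
augmented with the anchor cutoffs themselves so the step-function lookup
returns each printed pair exactly. The intermediate shape between anchors
is not published; the tables are plain data and should be regenerated
empirically (`build_fpr_table()`) by anyone with a benchmark.

The published overlap-ratio formula assumes segment i precedes segment j
and neither nests; we use the generalized intersection length
`min(b_i, b_j) - max(a_i, a_j)` (clamped at 0), which reduces to the
printed form in the intended configuration and behaves sensibly under
nesting. Orphan hits (one variant only) drop the 1/2 factor of the paired
coverage formula: the published worked example for a local-only hit
(coverage 0.42, measure FPR about 0.51, printed score 0.205) is consistent
with `(1 - fpr) * cov` and not with half of it; the halved reading remains
available (`halve_orphans = TRUE`). A side whose ratio measure is undefined
(remnant E-value underflow) is treated as absent for the ratio-based
coverage. When one sequence hits the same model several times, the
domain-wise score takes its best-supported hit (maximum coverage) before
averaging across sequences.

Pairing is greedy by descending overlap with a deterministic tie-break
(lower local-hit start, then lower glocal start); only the 0.9 threshold is
prescribed, the rest is implementation policy. Classification precedes
pairing, so FP/TN hits never enter a pair. The total FPR is a sum of two
error rates, not a probability; values above 1 occur and are reported
as-is.

## File formats and dialect conventions

The HMMER2 save format stores scores as integers scaled by 1000 (so
round-trip precision is 0.001 bits); the HMMER3 text format stores negative
natural logs of probabilities at five decimals. Two conventions make the
H3 dialect self-contained: the `COMPO` line doubles as the null model, and
the uniform local entry `B->M_k = -log2(K)` bits with zero exit terms is
reconstituted at parse time (the format does not store entry/exit). Writer
and parser share these conventions, so round-trips are exact to printed
precision; converting a glocal profile with non-uniform entry/exit into the
H3 dialect is refused rather than silently approximated. Profiles without
statistics lines parse into uncalibrated objects: alignment and scoring
work, any E-value computation fails loudly.

The search-report exchange format is a compact per-domain report (header,
`>>` line per domain with score/E-value/spans, explicit alignment path
line) modelled on the per-domain reports of the standard search programs;
the package both writes and parses it, and parsed alignments are validated
against the named profile.

## The synthetic benchmark: what it emulates and what it does not

`generate_benchmark()` builds, at toy scale, the structure of a
remote-homology benchmark: superfamilies mapped to domain models, member
sequences, decoys, and known truth labels. Each model is two fold-critical
blocks (12 columns each, consensus emission probability 0.7) flanking a
conserved low-complexity remnant block (30 columns, emission probability
0.95 on one residue), so the true mask is known by construction and the
remnant run survives the 10-column merge. Member sequences are the
consensus with 15% substitutions in the fold-critical blocks; half of them
(`fn_fraction = 0.5`) additionally have the remnant stretch replaced by a
different low-complexity run. That replacement costs the remnant sum about
4 bits per column while leaving the fold-critical sum essentially
untouched, which pushes the full score below the original-E cutoff while
the fold-critical E-value stays significant — exactly the planted
false-negative class that dissection is supposed to rescue. Decoys
(contamination 0.3 of the member count) are background-random sequences
with a model's remnant consensus planted, so their hits are
remnant-driven: original-E significant, fold-critical insignificant — the
planted false-positive class that dissection suppresses and an
original-E-filtered baseline admits at high coverage.

EVD parameters are calibrated per profile by scoring 1000 random background
sequences (length 1.2 K) and fitting a Gumbel by moments
(`lambda = pi / (sd sqrt(6))`, `mu = mean - gamma / lambda`); the fit is
bound as the forward exponential tail for the local dialect. Calibration
scores are match-terminated (a delete-terminated random path never beats a
match ending by more than the exit bookkeeping, and match termination keeps
the score-only recurrence simple and fast). The effective database size
defaults to 540,261 comparisons everywhere, overridable per run.

What passing on this benchmark shows: the pipeline's decision logic —
dissection, calibration, classification, pairing, coverage scoring —
separates fold-related from remnant-driven hits when the two signals are
planted separately. What it does not show: performance on real domain
families, where fold-critical/remnant structure is not block-wise, masks
are imperfect predictions, alignment uncertainty is larger, and the
negative-measure distributions are far broader. The published full-scale
sensitivity numbers are not reproducible at this scale and are not claimed;
the benchmark asserts *dominance* of the dissected coverage ROC over the
original-E baseline at FPR <= 0.15, aggregated over 20 seeded replicates.

## Numerical choices and problem sizes

* Ties in the Viterbi recurrences prefer match continuation, then insert,
  then delete, then a fresh entry; the best path is therefore
  deterministic, and equal-scoring end points prefer match endings.
* A pure-delete glocal path emits nothing and is rejected; termination
  falls back to the best path whose traceback passes through a match
  state.
* The delete-chain recurrence is unrolled into a prefix cummax (exact for
  finite transition costs, with a sequential fallback otherwise), and EVD
  calibration uses a batch dynamic programme vectorised across sequences.
* Test problem sizes: exhaustive path enumeration on models with K <= 4
  and sequences <= 6 residues; additivity and refinement properties on
  random K <= 10 fixtures; CDF recovery at n = 10,000 against the
  Dvoretzky-Kiefer-Wolfowitz 95% band; ROC dominance on 2 superfamilies x
  4 models x 4 member sequences per seed over 20 seeds. These sizes were
  chosen so the full suite exercises every code path in a few minutes while
  the statistical assertions retain enough power to fail on a real defect.

## Known limitations

* The mask predictors approximate two formulas whose published definitions
  are not reproducible (quality score, per-column label aggregation);
  external score vectors bypass both.
* The packaged anchor tables interpolate between printed anchor points;
  only the anchors themselves are authoritative.
* Dissected sums are evaluated against whole-alignment null statistics;
  this is the method's own convention, not an exact partial-score null
  model.
* The search-report parser targets the package's documented exchange
  format; outputs of other programs should be converted or re-aligned with
  `viterbi_align()`.
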