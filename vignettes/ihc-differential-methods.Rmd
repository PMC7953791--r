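---
title: "Methods: ranking IHC differentials and validating the ranker"
author: "ihcdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking IHC differentials and validating the ranker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcdiff)
```

## The problem

Immunohistochemistry read-outs are binary per marker, and the frequency
with which each marker stains positive in each neoplasm is empirically
documented. For a tumour of unknown origin, the diagnostic question is:
given a panel of positive/negative results, which diseases are most
compatible? `ihcdiff` answers it with a naive-Bayes ranker over a curated
disease × antibody positivity table.

## Model and assumptions

For disease $i$ and marker $j$ the knowledge base stores the positivity
$p_{ij} = P(\text{marker } j \text{ positive} \mid \text{disease } i)$.
The panel likelihood multiplies per-marker factors under **conditional
independence given the disease** — the central modelling assumption.
Real marker pairs can be strongly correlated (lineage programs drive
co-expression), so the product can over-count evidence; the ranking is
still usable because all candidates are distorted in the same direction,
but the posteriors should be read as scores, not calibrated probabilities.

Three numerical decisions make the product well-behaved:

* **Flooring** (`floor`, default 0.01). Curated vocabularies include 0%
  ("never") and high positives; a literal 0 factor would eliminate a
  disease on one atypical result, and atypical profiles are precisely the
  dominant real-world error source. Every positivity is clipped to
  $[\varepsilon, 1-\varepsilon]$ before use, so log-likelihoods are always
  finite. The floor is an inference device only — the synthetic generator
  samples from the *unclipped* values, because the generator emulates
  biology while the floor regularises inference.
* **Missing profile entries** (`missing_policy`, default `"impute"` with
  `impute_value = 0.5`). A marker never profiled for a disease contributes
  an uninformative 0.5 factor, which keeps likelihoods comparable across
  diseases whose profiles cover different marker subsets. The alternative
  `"skip"` drops the marker from that disease's product; it is offered for
  completeness but biased when coverage differs, because a product over
  fewer factors is systematically larger.
* **Log-space accumulation.** Likelihoods are summed as logs and
  normalised after subtracting the maximum, so panels of any length cannot
  underflow. On fixture scale the result equals the direct product to
  1e-9, which the test suite checks against a brute-force oracle.

The prior is uniform by default — pre-test incidence varies so much with
population and context that it is deliberately neglected — and an explicit
named prior is accepted for settings where incidence is known.

### Two scores

The displayed percentage of an expert-system differential need not be a
normalised posterior (two candidates can both show "64%"). The package
therefore reports both:

* `posterior` — prior-weighted likelihood normalised over the scored
  candidates; relative, sums to 1; the default ranking key.
* `concordance` — $100 (\prod f_j)^{1/m}$, the geometric mean of the
  per-marker factors; absolute per-disease fit, independent of the other
  candidates; the natural display score. Its exact published formula is
  not documented anywhere we could rely on, so this definition is our own,
  stated openly.

Ties break by descending `n_profiled` (prefer the better-evidenced
candidate) then ascending `disease_id` (determinism); both choices are
ours, as no tie rule is conventionally documented.

## Curation encoding

Qualitative textbook terms map to fixed fractions: always 0.95, often
0.75, about half 0.50, seldom 0.30, rarely/occasionally 0.10, never 0.
Conflicting sources are merged by unweighted arithmetic mean — the same
rule regardless of whether the sources are terms or numeric percentages,
since no principled weighting is available. Display grades bin the percent
scale half-open — $[75,100]$ `++`, $[50,75)$ `+`, $[30,50)$ `+/-`,
$[10,30)$ `-/+`, $[0,10)$ `--` — because integer ranges like "50–74%"
leave fractional values undefined; half-open bins make the mapping total.
Antibody matching lowercases, trims, collapses whitespace and treats
hyphen/space/slash as equivalent separators ("TTF1" ≡ "TTF-1"), the
dominant real alias pattern; beyond that, synonyms are explicit registry
entries.

## Validation protocol

`filter_cases()` applies the case-inclusion rules: prognostic-only markers
(EGFR, p53, Ki-67-style; flagged in the registry) are stripped because
they inform outcome rather than origin; cases with no diagnostic marker or
fewer than three markers after stripping are excluded, each with a
machine-readable reason; unparseable result tokens exclude a case as
inconclusive. `is_hit()` counts a case as accurate when the ground-truth
disease — or any disease in its *equivalence group*, entries differing
only by anatomical site such as gastrointestinal stromal tumour of stomach
versus small intestine — appears in the top-k (default 10) differential.
`evaluate_dataset()` tallies accurate/error counts per disease category;
rates are always recomputed from the exact integer counts and rendered to
one decimal. Error rates of two datasets are compared with the
**uncorrected** Pearson chi-square on the 2×2 accurate/error table: on the
published training-versus-validation totals (441/121 vs 298/84) the
uncorrected test gives $p = 0.8666$, matching the reported three-digit
value, whereas the Yates-corrected test gives 0.93 — hence the correction
is fixed off. `split_dataset()` provides the seeded 6:4 random split;
whether the original split was random or chronological is unknowable, so
seeded-random is the documented default.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` fixes the study-like conditions: panels of 1–13 markers
with mean 6.8 (a $1 + \mathrm{Binomial}(12, 0.483)$ size distribution —
bounded, integer-valued, and fully described by its mean and range; the
true dispersion of real panel sizes is unreported, so this is a documented
stand-in); positivity values on the six-value curation vocabulary; each
disease carrying two *specific* markers (0.95 in the disease, ≤0.10
wherever profiled elsewhere); results Bernoulli-sampled from the profile
and flipped with probability `atypicality_rate`. Defaults chosen once: 20
diseases × 60 antibodies with 13–20 profiled markers per disease, so every
profile supports a full-size panel and the panel-size mean is not
truncated; atypicality 0.1 as a realistic baseline contradiction rate.

Two switches define the clean-recovery regime used in testing:
`vocabulary = c(0, 0.95)` (maximally distinctive profiles) and
`exact_sampling = TRUE` (sampling probabilities clipped to exactly 0/1, so
with zero atypicality every result matches its profile sign — the
noise-free limit). Under that regime the true diagnosis is recovered in
the top 10 for ≥99% of 500 generated cases and at rank 1 for ≥95%;
with honest Bernoulli sampling at the stored 0.95 the specific markers
themselves contradict their profile in ~10% of cases and top-10 recovery
settles near 97%. Hit rate falls monotonically as the atypicality rate
rises through 0–0.3, and duplicating a profile under a second identifier
measurably depresses top-1 (but not top-2) recovery — the
overlapping-profile error mechanism.

What the generator does **not** emulate: marker–marker correlation (the
ranker assumes it away, so simulated data cannot probe that
misspecification), organ-incidence case mixes, mixed/combined tumours, and
the scale of a real curated database (thousands of diseases, hundreds of
antibodies). Passing synthetic tests therefore demonstrates correctness of
the machinery and the model's behaviour under its own assumptions — not
clinical accuracy on real cases.

## Problem sizes and determinism

The test suite runs on fixture-scale knowledge bases (≤6 × ≤6 for the
brute-force oracle comparisons, 200 random draws; 20 × 60 for simulation
properties, 500 cases per condition and five seeds per atypicality level),
sizes at which the oracle and the log-space path agree to 1e-9 and
Monte-Carlo noise on a hit rate is below one point. All generation and
splitting is seeded and restores the caller's RNG state; identical
spec + seed reproduces byte-identical fixture bundles.

## Known limitations

* Posteriors inherit the conditional-independence distortion; use ranks.
* The concordance definition is this package's stand-in for an
  undocumented display formula.
* Knowledge bases are authored, not fitted: nothing here learns
  positivities from labelled cases.
* The mean-merge rule treats all sources equally; no recency or sample
  size weighting.
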