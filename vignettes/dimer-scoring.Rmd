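---
title: "Scoring primer dimers, setting dimer-free thresholds, and building multiplex pools"
author: "oligodimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring primer dimers, setting dimer-free thresholds, and building multiplex pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligodimer)
```

## The problem

Primer-dimers are off-target PCR products formed when two primers hybridise
to each other and the polymerase extends the complex. They consume primers
and dNTPs, compete with the target amplicon, and are the main failure mode
of multiplex PCR, where the number of possible primer-primer interactions
grows as $(n^2+n)/2$ with the number of primers $n$. The practically
dangerous species are *extensible* dimers: structures whose 3' terminus is
stably base-paired, so the polymerase can elongate. Non-extensible
primer-primer binding is deliberately outside the model.

`oligodimer` does three things:

1. **Scores** a primer pair for extensible-dimer propensity with a
   $\Delta G$-based dimer score (`dimer_score_pair`).
2. **Evaluates** how well that score discriminates empirically labeled
   (gel-called) dimer-forming from dimer-free pairs with a ROC curve, and
   reports a *dimer-free threshold* with zero false negatives
   (`evaluate_dataset`, `build_roc`, `dimer_free_threshold`).
3. **Designs** multiplex primer pools greedily so that every pairwise
   interaction clears the dimer-free cutoff (`build_pool`, `verify_pool`).

## The dimer score

Given two oligos written 5'→3', the longer is the *top* strand and the
shorter, reversed into 3'→5' orientation, the *bottom*. The bottom's 3' end
starts paired against the top's 5' end (a single 3' overhang, unless the
lengths are equal) and slides rightward one position at a time, generating
every ungapped alignment with 5' overhangs down to a minimum overlap of 2
bases (one nearest-neighbour step). The bottom's 3'-terminal base is paired
in every enumerated structure, which is exactly the extensible geometry.

Each structure is scored as follows.

* **Base value.** Every adjacent pair of aligned positions is a
  nearest-neighbour step with a free-energy contribution: Watson-Crick
  steps from the unified duplex table, steps with exactly one mismatched
  position from the published single-mismatch tables, and doubly mismatched
  steps a configurable destabilising penalty (default +1). Running prefix
  sums of these step $\Delta G$s are scanned inward from *each* of the two
  3'-terminal overlap positions independently; the more negative of the two
  prefix minima is the structure's base value. This rewards exactly the
  stable-3'-anchor geometry seen in sequenced dimer artefacts.
* **3'-end penalties.** Mismatches at overlap positions 1-5 counted from
  the scored (winning) 3' end add per-position penalties (defaults
  +3, +3, +2, +1, +1); if position 1 or 2 is a mismatch and at least one
  more mismatch falls in the first five, a compound end penalty (default
  +2) is added.
* **5' overhang terms.** A dangling base adjacent to a terminal matched
  pair contributes its published 5' dangling-end $\Delta G_{37}$.
* **Full-span G/C bonus.** A structure that spans both 3' ends with every
  position matched, terminating in C or G at the scored end, receives a
  stabilising bonus (default −1).

The most negative structure score across all offsets of the three possible
pairings (forward-reverse plus both homodimers) is the pair's raw dimer
score, initialised at the sentinel 100 when nothing alignable exists. The
per-position penalty magnitudes, compound penalty, double-mismatch penalty
and bonus are not physical constants; they are empirical weights, exposed
in `scoring_config` and re-derivable with `grid_search`.

Scanning from *both* 3'-terminal overlap positions and taking the more
negative minimum was a genuinely open design point; we adopted it because
each end of a dimer structure is an independent potential extension site.
Ties between the two scans resolve to the bottom strand's 3' end. Penalties
are counted from the winning end only: a mismatch near the end that is not
being extended does not impede extension at the other end.

### Length/GC adjustment

Raw scores grow with primer length and G+C content, so a 30-mer fusion
primer and an 18-mer genomic primer are not comparable on the raw scale.
The adjusted score is

```
ds <- ds / 20 * (len_top + len_bottom)
ds <- ds + ds * gc_avg * 2.25
ds <- ds / 4.4
```

where `gc_avg` is the mean of the two primers' G+C *fractions*. We read the
"average GC count" of the defining pseudocode as a fraction, not an integer
count: a count would inflate scores ten- to twenty-fold, defeating the
stated purpose of keeping the result comparable to a free energy.
`adjust_length_gc(-4.4, <two GC-free 10-mers>)` is exactly −1.0, which
pins all three constants.

```{r}
params <- thermo_params()
config <- scoring_config()
pair <- primer_pair("demo", "ACGGTCAGTCAGGCAT",
                    reverse_complement("ACGGTCAGTCAGGCAT"))
dimer_score_pair(pair, params, config)
```

## Thermodynamics

Parameter tables ship as plain TSV files under `inst/extdata` (and can be
replaced by the user): the unified Watson-Crick duplex set (all 16 step
keys; $\Delta G^\circ_{37}$, $\Delta H$, $\Delta S$), the internal
single-mismatch compilations, and the 5' dangling-end set. At the standard
condition (37&nbsp;°C, 1&nbsp;M Na⁺) the tabulated $\Delta G^\circ_{37}$
values are used as-is; under any other condition each step is recomputed as
$\Delta H - T\,\Delta S_{\mathrm{Na}}/1000$ with the entropic salt
correction $\Delta S[\mathrm{Na^+}] = \Delta S[1\,\mathrm{M}] +
0.368\,(N/2)\ln[\mathrm{Na^+}]$ applied per step ($N = 2$ phosphates).
Magnesium contributes through a sodium-equivalent concentration
$[\mathrm{Na^+}] + 0.120\sqrt{[\mathrm{Mg^{2+}}]_{free}}$ (mol/L), with
dNTPs chelating magnesium stoichiometrically. For the common PCR buffer of
50&nbsp;mM monovalents and 4.5&nbsp;mM Mg²⁺ this gives ≈0.30&nbsp;M
sodium equivalent. Temperature and pH-active additives such as TMAC, CES or
formamide have no representation in the nearest-neighbour model; scores are
not adjusted for them, which is precisely why the ROC-based threshold (which
renormalises against the user's own labeled data) is the condition-robust
quantity, rather than the score itself.

Two deliberate restrictions: 5' dangling-end terms are applied at their
37&nbsp;°C values regardless of conditions (the cited dataset is tabulated
as $\Delta G^\circ_{37}$), and single-mismatch steps missing from the
published compilations fall back to 0&nbsp;kcal/mol with a one-time warning
(with the shipped tables the compilation is complete, so the fallback only
triggers for user-supplied table files).

## ROC evaluation and the dimer-free threshold

Scores paired with gel labels are swept from most positive to most
negative; each observed score (plus a sentinel above the maximum) becomes a
discrimination threshold, classification being *dimer* strictly below the
threshold and *dimer-free* at or above it. TPR and FPR at each threshold
trace the curve; the area accumulates by the trapezoid rule, which treats
cross-class ties as diagonal segments and therefore reproduces the
tie-corrected Mann-Whitney statistic exactly (this identity is asserted in
the tests). The stored points run from the sentinel threshold at (1,&nbsp;1)
down to the minimum score at (0,&nbsp;0).

The *dimer-free threshold* is the score below which the first
dimer-forming pair appears: the lowest observed score strictly above every
dimer-labeled score. At that cutoff the false-negative count is zero by
construction, and the TNR (the fraction of dimer-free pairs at or above the
cutoff) measures how much of the safe design space survives. Whether one
should report the adjacent dimer-free score (our default) or the worst
dimer score itself is not decidable from first principles; both are
available (`threshold_rule = "above_worst_dimer"` / `"worst_dimer"`).
Ambiguous gel calls are excluded by default; the stringent mode
(`ambiguous_mode = "as_dimer"`) reclassifies them as dimer-forming.

The shipped multiplex default threshold of −4.43 (adjusted scale) is the
cutoff calibrated on gel-labeled data under one specific PCR chemistry; it
is a condition-specific default, and users should re-derive their own from
labeled pairs run under their own conditions.

## Calibration by grid search

`grid_search` exhaustively scores every candidate combination of penalty
and bonus values on labeled training sets, maximising the mean dimer-free
TNR with mean AUC as tie-break, and remaining ties resolved to the first
configuration in the declared enumeration order. Exhaustive enumeration
(rather than coordinate descent) keeps the winner reproducible; a
structure-level feature decomposition (base value, per-position mismatch
indicators, compound flag, overhang sum, full-span flag) is precomputed
once per pair, so only the cheap linear combination is recomputed per
configuration. Aggregation across multiple training sets is an unweighted
mean.

## The synthetic data generator

The generator emulates gel-labeled primer sets. Dimer-class pairs carry a
planted mutual 3'-complementary block of 8-12 bases in one of the two
artefact geometries observed in sequenced dimers — perfect complementarity
spanning both 3' ends, or a single 3' end annealing to an internal block
with a 5' overhang — chosen at random per pair. Dimer-free pairs are
rejection-sampled so that no pairing (hetero or homodimer) contains a
complementary run of four or more bases anywhere. Because a handful of
published single-mismatch steps are themselves stabilising (G·T and G·A
wobbles), sequence-level rejection alone cannot bound the score of a
"clean" pair; since the gel label the generator emulates is itself a
readout of duplex stability, class membership is additionally confirmed
thermodynamically: dimer pairs must score at or below −5 (adjusted) and
dimer-free pairs at or above −4, leaving a one-unit margin between the
classes. With zero label noise the two score distributions therefore do not
overlap by construction (AUC = TNR = 1), which is what the separation
tests assert; label noise then flips labels independently at the requested
rate. Generation is deterministic given the seed; default sizes (200
pairs, 30% dimer fraction, 18-24-base primers at 35-65% G+C) mirror a
typical labeled validation set.

What the generator does *not* emulate: fusion-tail composition bias,
bisulfite-converted base composition, non-extensible dimers, gel-calling
ambiguity (beyond the noise rate), and cross-pair correlation within a
plate. A perfect score on synthetic data therefore demonstrates internal
consistency of scorer + ROC + threshold machinery, not field accuracy on
laboratory primer sets.

For parameter-recovery experiments, `generate_calibration_set` builds a
set whose labels are perfectly separated *under a chosen planted
configuration*: probe pairs sensitive to the full-span bonus (intact 3'-3'
blocks) and to the compound penalty (single-end blocks with mismatches
planted at positions 2 and 4 from the scored end) are mixed with clean
pairs, scored under the planted configuration, and labeled at a cutoff
placed so that every competitor configuration provably misorders at least
one pair. Scores are monotone in each penalty coefficient (the score is a
minimum of linear functions with non-negative feature weights), so
defeating the nearest perturbation on each side of a parameter defeats all
larger ones. The cutoff search redraws deterministically (up to ten times)
if a drawn set admits no such cutoff.

Multiplex fixtures (`generate_multiplex_fixture`) define orthogonality
operationally: each candidate pair is rejection-sampled (after a fast
3'-complementarity pre-filter) until all of its interactions — its own
three pairings, its region mates, and every primer generated before it —
score at least 0.5 above the dimer-free cutoff, so a fully orthogonal
fixture is orthogonal for any seed, not just probabilistically. The
adversarial variant instead plants the reverse complement of an earlier
region's primer at a later candidate's 3' end, forcing a dropout.

## Multiplex pool construction

Regions are processed from fewest to most candidates (ties by region id),
the intuition being that constrained regions should claim their slots
before the pool fills. For each region, every candidate's worst interaction
against the growing pool (own pairings included) is computed; candidates at
or above the threshold survive, and the best-scoring survivor joins the
pool. Earlier acceptances are never rescored — the greedy, no-backtracking
reading — which is why `verify_pool` exists: it exhaustively rescoring all
$(n^2+n)/2$ primer-primer combinations of the final pool and confirms none
falls below the threshold.

## Numerical choices and edge cases

* Scores are plain doubles; structure enumeration order (by offset, within
  pairing order FR, FF, RR) and first-minimum tie-breaking make every
  result bit-reproducible.
* Equal-length oligos: the first argument becomes the top strand; the
  scorer is symmetric under swapping forward and reverse, so the choice is
  unobservable.
* Pairs too short to form a 2-base overlap keep the sentinel score 100 and
  skip the length/GC adjustment.
* ROC construction rejects single-class and non-finite inputs; the
  vacuous no-dimer case reports the minimum observed score with TNR 1 and
  a `vacuous` flag.
* Sorting of ROC points uses distinct observed scores only, so duplicated
  scores cannot produce zero-width trapezoids.
* Problem sizes used in the shipped tests (500 oracle pairs of up to 10
  bases, 1000 small ROC instances, 200-pair synthetic sets, a 10-region
  pool) were chosen as the smallest sizes that exercise every code path
  and tie-break; all are package choices and scale linearly if enlarged.

## Known limitations

* The empirical penalty/bonus defaults were fixed by the package authors'
  choice, not fitted to laboratory gel data; users with labeled sets
  should calibrate with `grid_search`.
* Hairpins, template mispriming, Tm balancing and primer design itself are
  out of scope; the multiplex builder consumes externally designed
  candidates.
* The nearest-neighbour model cannot represent pH, TMAC/CES/formamide, or
  polymerase effects; the ROC threshold machinery is the intended remedy.
* The Mg²⁺-to-sodium equivalence is the square-root rule used across the
  primer-tool ecosystem; other published equivalences differ by a few
  percent at PCR-typical concentrations.
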