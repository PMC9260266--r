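---
title: "MSAP methylation analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSAP methylation analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapr)
```

## The assay and its observation model

MSAP digests genomic DNA twice: with EcoRI + HpaII (the *H* digest) and
with EcoRI + MspI (the *M* digest). HpaII and MspI recognize the same
CCGG site but respond differently to cytosine methylation: HpaII is
blocked by methylation of either cytosine on both strands (it tolerates
hemi-methylated external cytosines), while MspI cuts C^mCGG but is
blocked by ^mC methylation of the external cytosine. A scored band
therefore means "this enzyme cut here", and the pair of flags per locus
encodes one of four observable patterns:

* **I** (1,1) — unmethylated;
* **II** (1,0) — hemi-methylated;
* **III** (0,1) — internal cytosine fully methylated;
* **IV** (0,0) — hypermethylation that blocks both enzymes.

Two assumptions are inherited from the assay, not chosen by this package:
bands are scored as clean binaries (gel intensity is upstream of us), and
co-migrating fragments are the same locus in all lanes (no fuzzy band
matching; a band-size tolerance would model gel artifacts we cannot see
from a binary matrix).

## Methylation levels

Pattern IV is invisible to both digests — a (0,0) locus may be
hypermethylated, absent, or a primer mismatch — so levels are computed on
the detectable classes only:

$$\mathrm{total} = 100\,\frac{n_{II}+n_{III}}{n_I+n_{II}+n_{III}},\qquad
  \mathrm{hemi} = 100\,\frac{n_{II}}{n_I+n_{II}+n_{III}},\qquad
  \mathrm{full} = 100\,\frac{n_{III}}{n_I+n_{II}+n_{III}}.$$

`methylation_levels()` keeps full floating-point precision and leaves
rounding to the caller; the identity hemi + full = total then holds to
1e-9 by construction (exactly, up to floating-point addition). If every
locus in a group is pattern IV the denominator is zero and the function
raises an explicit error rather than returning `NaN`.

## Transition typing

For a control/treatment comparison the 16 ordered pattern pairs partition
structurally by what happens to the H band:

* H band **lost** → methylation gain, types **B1–B4**
  (I→III, II→III, II→IV, I→IV);
* H band **gained** → demethylation, types **C1–C4**
  (III→I, III→II, IV→II, IV→I);
* H unchanged, M changed (I↔II, III↔IV) → **AMBIGUOUS**: MSAP cannot sign
  these changes, so they are counted and reported but excluded from the
  gain/loss totals;
* both unchanged → **UNCHANGED**.

The partition is 4 + 4 + 4 + 4 and the test suite verifies it by
exhaustive enumeration. `summarize_transitions()` reports the B and C
totals, the dominant type on each side (ties are reported together,
comma-separated), and the number of loci compared, which the ten type
counts always conserve.

Comparisons pair loci by identifier after replicate consensus; each input
must hold a single consensus sample, which keeps the pairing unambiguous.

## Replicate consensus

Published MSAP designs typically run three biological replicates but
rarely state how they were merged. `aggregate_replicates()` makes the
policy explicit: the default is strict majority per band flag, with exact
ties resolved to 0 (band absent) and a warning — a band call should
require positive evidence, and silent tie-breaking toward presence would
inflate methylation-change counts. `any` and `all` policies are available
for sensitivity analysis. Missing calls (`NA`) are dropped from the vote;
a cell with no informative replicate stays `NA` and is excluded (with a
message) from downstream counts.

## The synthetic-data generator

`simulate_experiment()` is first-class, tested code: it provides ground
truth the real study cannot (per-locus methylation states), so the scoring
and transition machinery can be validated end-to-end.

The generative model, per locus:

1. a control state is drawn from `state_probs` over {UNMETHYLATED, HEMI,
   INTERNAL_FULL, HYPER};
2. under dose $d$ (µM), the locus takes **one** demethylation step with
   probability $p(d) = 1 - e^{-\kappa d}$: HYPER → HEMI or INTERNAL_FULL
   (equal odds), INTERNAL_FULL → UNMETHYLATED, HEMI → UNMETHYLATED;
   independently a locus gains one step with probability `gain_prob`
   (UNMETHYLATED → HEMI or INTERNAL_FULL with equal odds, HEMI → HYPER; a
   HEMI locus that demethylated in the same round keeps the
   demethylation);
3. states render deterministically to band profiles (the digestion table
   above), and each emitted replicate flips each flag independently with
   probability `call_error`.

One step per treatment round — rather than equilibrium kinetics — is the
simplest mechanism that reproduces the qualitative observations of
5-azaC studies (demethylation dominating gains, IV→II prominent when
hypermethylated loci are common) while staying analytically tractable:
the treatment is a 4×4 Markov kernel against which the test suite checks
simulated transition-type frequencies exactly. The exponential
dose-response is a smooth, saturating, single-parameter choice; no
functional form is published for passive 5-azaC demethylation at this
resolution.

Defaults (chosen once, as a realistic plant-MSAP scenario, before any
validation was run): `state_probs = (0.45, 0.20, 0.15, 0.20)` — roughly
half of CCGG sites methylated in some form, hemi-methylation exceeding
full methylation as commonly observed in plant genomes; `doses = 0, 15,
50, 100` µM (the standard 5-azaC series); `kappa = 0.01`/µM, giving step
probabilities 0.14/0.39/0.63 across that series — a clearly
dose-dependent effect without saturation at the lowest dose; `gain_prob =
0.02`, making gains rare relative to losses (as observed in
demethylating-agent experiments); `call_error = 0.02`, a plausible
per-band miscall rate that replicate consensus is designed to absorb;
three replicates.

What the simulator does **not** emulate: sequence-level CCGG placement,
fragment lengths or primer selectivity; correlated miscalls (gel-lane
effects hit many bands at once, while our noise is independent);
between-replicate biological variance (replicates share the locus state
and differ only in call noise); and context-dependent demethylation
rates. Passing tests therefore certify the scoring/transition logic and
the statistical behaviour of the estimators under this model — they are
not evidence about gel scoring quality in real data.

Randomness: one master seed is split up front into one sub-seed per dose
(state process) plus one per dose × replicate (call noise), all drawn
from the master seed before any use, so outputs are bit-reproducible and
adding doses or replicates does not reshuffle earlier draws. `kappa` can
be recovered from ground truth by inverting the observed step fraction at
one dose (`estimate_kappa()`), which the suite requires to land within
10% at 10,000 loci.

## Quantitation conventions

**2^−ΔΔCt.** ΔCt is target minus reference per sample; ΔΔCt subtracts the
*group-mean* ΔCt of the control (the standard Livak formulation) rather
than averaging per-sample fold changes — the two differ under Jensen's
inequality and the group-mean version makes the control fold exactly 1.
The control group is an explicit argument: normalization scope (within
tissue or across) is a design decision the caller must own.

**5mC%.** No single formula is standard for HPLC chromatograms; we
implement the corrected molar fraction
$100\,(A_{5mC}/f_{5mC})/(A_{5mC}/f_{5mC} + A_C/f_C)$ with response
factors defaulting to 1 and overridable from calibration standards. This
is documented as a convention; peak integration is out of scope.

**Duncan's multiple range test.** After a one-way ANOVA, means are sorted
in decreasing order and a pair spanning $p$ ranks differs when its
difference exceeds $R_p = q\!\left((1-\alpha)^{p-1};\, p,\,
df_e\right)\sqrt{MS_e/n_h}$ — Duncan's protection level applied to the
studentized-range quantile (`stats::qtukey`), with $n_h$ the harmonic
mean of all group sizes (only relevant for unbalanced data; the typical
three-replicate design is balanced). The sequential rule that a pair
inside a non-significant span is itself non-significant is enforced by
zeroing from the widest span inward, which the tests verify against the
quantified textbook definition (a pair differs iff *every* enclosing
range exceeds its critical value). Letters come from the
insert-and-absorb compact-letter-display algorithm, ordered so `a` sits
on the largest mean — matching the figure convention of marking bars with
letters. Degenerate inputs (zero within-group variance, detected exactly
before fitting) raise an error rather than emitting letters from an
undefined $MS_e$; with *near*-zero variance (e.g. jitter at 1e-9) the
test is well-defined and all groups share a letter unless means truly
separate.

## Numerical and formatting choices

* Co-occurrence rates are kept exact and *also* reported rounded to one
  decimal, **half away from zero**: base R's round-half-even would print
  22/72 as 30.5 and 28/72 as 38.8, while published tables of this kind
  print 30.6 and 38.9.
* Band files admit only literal `0`/`1`/`NA` cells; all other values are
  rejected with errors naming the locus and column. Validation is total:
  nothing is coerced silently.
* All CLI outputs are written to a temporary file and renamed on success,
  so a failing run never leaves a partial result; TSVs carry `#`
  provenance comments (version, parameters, input MD5s) that the readers
  skip transparently.

## Problem sizes

The test suite validates distributional claims at the sizes where the
binomial/multinomial bounds are meaningful but fast: 10,000 loci for
state-frequency recovery and rate-constant estimation (3σ multinomial
bounds, 10% relative error), 100,000 draws for the single-step binomial
law, 20,000 loci for the kernel-closure and dose-monotonicity checks, and
1,000 random count vectors for the level-formula identities. The whole
suite runs in well under a minute.

## Known limitations

* MSAP only surveys CCGG sites and cannot see methylation that blocks
  both enzymes changing into other both-blocked configurations; the
  AMBIGUOUS class is the honest boundary of the assay, and `msapr` never
  imputes a direction for it.
* `transition_table()` requires identical locus sets; there is no
  cross-gel band reconciliation.
* No amplification-efficiency correction for qRT-PCR (Pfaffl-type
  models) — Ct data are taken at face value.
* The transition report is purely descriptive; no significance test is
  attached to transition counts.
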