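---
title: "Methods: differential essentiality in isogenic drop-out screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential essentiality in isogenic drop-out screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscreen)
```

## The problem and the model

A pooled drop-out screen infects a cell population with a genome-wide
sgRNA library and lets selection act: guides against genes required for
growth deplete relative to the plasmid library over ~16 population
doublings. Run in an isogenic pair — three clonal knockout lines and
three wild-type lines from the same parental line — the screen can
separate *background-specific* dependencies from plain essentiality.

The analysis chain is:

1. **Counting.** Reads are matched to spacers exactly (no mismatches).
   The library validator rejects duplicated spacers outright, so a read
   can never be attributed to two guides and no tie-break is needed.
   Conservation (matched + unmatched + short = total) is asserted in
   tests for every counting path.

2. **Fold change.** `fc = log2[(c+α)S/D] − log2[(c_p+α)S/D_p]` with
   defaults α = 5, S = 1e7 (reads per 10 million with pseudocount 5,
   standard practice for BF-style screen scoring). α > 0 keeps zero
   counts finite; S cancels in the difference.

3. **Bayes factor.** Per replicate line, Gaussian-kernel densities are
   fitted to the fold changes of training essential / non-essential
   genes (Silverman bandwidth; density floor 1e-12), and a gene's BF is
   the sum of `log2 p_ess/p_non` over its guide observations. The three
   lines per genotype are scored separately and combined by arithmetic
   mean (median available). Positive BF (bits) means the gene's guides
   behave like essential-gene guides.

4. **Residual Z.** OLS with intercept of knockout BF on wild-type BF,
   one point per gene; `Z = (r − mean r)/sd r` with the population-sd
   convention (the literal reading of "sd of all residuals"; the sample
   convention is a flag — at genome scale the two are indistinguishable,
   and the toy-scale tests pin the default). Calls use the strict rule
   `Z > 3.5`; ties at the threshold are excluded; ranks break Z-ties
   alphabetically so output is deterministic.

## Numerical choices that matter

**The evaluation clamp.** A kernel density estimate is meaningless far
outside its training cloud: with only a floor, a single fold change in
the deep tail yields a ±30-bit likelihood ratio and one noisy guide can
dominate a gene's score. Evaluations are therefore clamped into
`[lo, hi]`, where `lo` is the leftmost point at which the non-essential
density still exceeds 2⁻⁷ and `hi` is the log-ratio minimum right of
`lo` (preventing the ratio from spuriously rising again where the
non-essential density collapses). Measured on simulated screens, the
clamp cuts spurious calls roughly five-fold without affecting recovery
of planted effects. `clamp_eps = NULL` disables it.

**Bootstrap default.** `gene_bayes_factor(boot = n)` refits the
densities on training genes resampled with replacement and reports the
bootstrap mean and sd. The default is `boot = 0`: at desk scale a
200-iteration bootstrap multiplies the dominant cost (kernel evaluation
over every guide × line) by 200 and adds little at the training sizes
used here; the plain fit is already deterministic. Enable it when
training sets are small or suspect.

**Intercept.** The linear model includes an intercept. Because the Z
formula re-centres residuals anyway, the distinction from a
through-the-origin fit is minor; with an intercept the residuals sum to
zero exactly, which the tests exploit as an invariant.

**Replicate handling.** Likelihood ratios are summed within a line and
lines are averaged per genotype (rather than averaging fold changes
before scoring). Both orders are implementable through the public
surface; summing preserves BF additivity over observations, which is
asserted directly in tests.

## What the simulator emulates — and what it does not

`sim_config()` encodes the screen design this package targets: 3–5
guides per gene plus non-targeting controls, infection at 200 cells per
guide with ~30% transduction efficiency (so virtually no cell carries
two guides), drug selection from day 2, ~16 doublings to day 21, at
least 500 cells per guide maintained at passaging, three clonal lines
per genotype plus the plasmid reference, and a fixed per-sample
sequencing depth (desk default 5e6 over 2000 genes; a genome-scale
configuration is a parameter change, not new code).

The generative model: plasmid guide weights are LogNormal(0, 0.5); each
infected cell is a true knockout with probability equal to its guide's
efficiency *e* ~ Beta(5, 2) (most guides effective, a tail of poor
ones); knockout cells grow as `2^{d(1+f)}` against `2^d` for escapers,
so an isolated guide's expected fold change is
`log2[e·2^{df} + (1−e)]`; infection, passaging and sequencing are
binomial/multinomial subsamples at the configured cell numbers.
Planted truth classes: `neutral`, `core_essential` (f = −0.3 in both
genotypes), `ko_specific` (f = −0.2, knockout only), `wt_specific`, and
`enriched_on_loss` (f = +0.1 in the knockout, mirroring guides that
*gain* abundance when an apoptosis brake is removed). The escaper
mixture is deliberate: cells that dodge editing repopulate the culture,
which is exactly what competitive-depletion follow-ups observe. Effect
sizes are chosen for detectability at desk scale — no published dropout
trajectory pins them — and are stated once here, not tuned per test.

A deterministic mode replaces every draw by its expectation; the
closed-form fold changes above then hold to the compositional
renormalization (≤ 0.01 when the affected library fraction is ≤ 0.1%),
which is how the growth model is unit-tested.

Not modelled: copy-number cutting artifacts, off-target toxicity,
double infection beyond the transduction filter, batch/line effects
beyond sampling noise, and PCR jackpotting. A green recovery test
therefore establishes that the *statistics* behave as specified on data
matching their assumptions — not that a real screen of this design will
reach the same precision.

## Known limitations

- **The Z > 3.5 null bound.** Z scores are standardized over the ~2000
  modelled genes, so the threshold sits at the null extreme-value scale:
  the expected maximum of 2000 standard normal draws is ≈ 3.54, and even
  a perfectly Gaussian residual field produces ≥ 1 spurious call in
  roughly a third of screens (expected count ≈ 0.5). Kernel
  self-scoring and guide-count/abundance heterogeneity add mild
  kurtosis (measured ≈ 3.7), giving ~2–3 spurious calls per null screen
  at desk scale. The acceptance test that demands ≤ 1 false call in 95%
  of null screens is kept red rather than weakened: no implementation
  of this statistic can meet it. Interpret the threshold as a ranking
  device, not an error-rate guarantee; control guides and replicate
  screens are the practical false-call guards.
- Training sets are user-supplied (or derived from planted truth in
  synthetic runs); the package ships no reference essentialome.
- Exact matching only: reads with sequencing errors inside the spacer
  are counted as unmatched, biasing depth slightly downward but not
  differentially between samples.
- The BF stage is a configurable re-specification of the
  kernel-density likelihood-ratio approach, not a bit-compatible port
  of any particular external tool.
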