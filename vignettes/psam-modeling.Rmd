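---
title: "Inferring sequence-to-affinity models from protein binding microarrays"
author: "psamfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sequence-to-affinity models from protein binding microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psamfit)
```

## The model

A transcription factor binding a DNA sequence $S$ at thermodynamic
equilibrium is characterised by an association constant $K_a(S)$.
Relative to a reference sequence $S_\mathrm{ref}$ (the highest-affinity
site), specificity is fully described by the binding free-energy
difference $\Delta\Delta G(S)$:

$$\frac{K_a(S)}{K_a(S_\mathrm{ref})} = e^{-\Delta\Delta G(S)/RT}.$$

`psamfit` models $\Delta\Delta G$ as additive over *sequence features* of
the length-$L$ binding window: one mononucleotide feature per position
(the exponentiated values per position form the columns of a
position-specific affinity matrix, PSAM), optionally extended by
adjacent-dinucleotide features that capture nearest-neighbour
dependencies (a feature-specific affinity model, FSAM). Within each
mononucleotide block the reference base is anchored at
$\Delta\Delta G = 0$; dinucleotide blocks use the scale-based convention
described below. All free energies are stored and fitted as the
dimensionless ratio $\Delta\Delta G/RT$ — the two quantities never occur
separately.

A PBM probe of fixed length offers the protein many binding *views*: one
placement per offset per strand, the reverse-strand view at an offset
being the reverse complement of the forward window there. The measured
fluorescence intensity is modelled as

$$y(S) = \beta_0 + \beta_1 \sum_v \gamma_v\, e^{-\Delta\Delta G(S_v)/RT},$$

where the per-view coefficients $\gamma_v$, shared across all probes,
absorb the microarray's positional and orientational bias: a site close
to the glass substrate or at the free end of the probe contributes less
to the signal than one in the middle. We fix $\max_v \gamma_v = 1$ and
fold the overall scale into $\beta_1$; the two are otherwise confounded.

At high protein concentration the brightest probes saturate. The
optional occupancy-form model replaces each view's contribution with
$x_v/(1+x_v)$, where

$$x_v = c\,\gamma_v\, e^{-\Delta\Delta G(S_v)/RT} + e^{-\Delta\Delta G_\mathrm{ns}/RT},$$

with $c$ a free-protein concentration scale and
$\Delta\Delta G_\mathrm{ns}$ a non-specific binding term. We read the
occupancy bracket strictly as $x_v/(1+x_v)$ — the only parsing consistent
with the fractional-occupancy form $[P]K_a/([P]K_a+1)$ — and the
non-specific term is not multiplied by $\gamma_v$. Both choices are
deliberate and documented here because the algebra admits other
readings.

## The fitting pipeline

1. **Seed discovery.** Probe intensities are fit as a weighted sum of
   two-strand K-mer counts ($K = 8$ by default). Coefficients start at
   $10^{-4}$ (non-specific background); each iteration computes, per
   oligomer and per probe containing it, the coefficient that would
   reproduce that probe exactly, takes the 15%-trimmed mean across
   probes, clips negatives to zero, and moves the coefficient a step
   $\alpha = 0.1$ towards it. The top oligomer (merged with its reverse
   complement, ties broken lexicographically) seeds the model.
2. **Block-wise robust PSAM estimation.** With the seed as reference,
   each position's four mononucleotide features form a *block*. Holding
   all other blocks fixed, the per-probe regressor of a feature is the
   bias-weighted sum of $e^{-(\Delta\Delta G(S_v) - \Delta\Delta
   G_\phi)/RT}$ over the views containing it; robust regression yields
   coefficients $\beta_\phi$, converted back through $\Delta\Delta
   G_\phi/RT = -\log(\beta_\phi/\beta_\mathrm{PSAM})$ and re-anchored so
   the reference base sits at zero. Blocks are cycled left to right
   until the largest change drops below $10^{-4}$ (at most 20 passes).
3. **Positional bias.** Intensities are robustly regressed on the
   per-view affinities, one shared coefficient per view; negatives are
   clipped, the profile normalised to maximum 1, and the scale moved
   into $\beta_1$. Steps 2-3 alternate until the free energies stop
   changing (outer tolerance $10^{-3}$).
4. **Dinucleotides.** $\beta_\mathrm{PSAM}$ — the value of $\beta_1$ at
   the end of the mononucleotide phase — is frozen, and the $L-1$
   dinucleotide blocks (16 features each) are cycled the same way, with
   conversions against the frozen scale. Under this convention most
   dinucleotide values land near zero and no anchor is imposed; the
   mononucleotide matrix is kept fixed during this phase. Weakly
   informed dinucleotide features can oscillate between the ceiling and
   small values, so dinucleotide cycling is capped at 5 passes and 3
   outer rounds — well past where the well-informed features converge.
5. **Optional saturation stage.** Levenberg-Marquardt
   (`minpack.lm::nlsLM`) fits $\beta_0$, $\beta_1$,
   $\Delta\Delta G_\mathrm{ns}$ and the concentration scale $c$
   (log-parametrised), starting from the linear stage with
   $\Delta\Delta G_\mathrm{ns}$ large and $c = 1$; robust-stage probe
   weights carry over, and non-convergence falls back to the linear
   parameters with a warning.

### Robust regression

Every regression above is iteratively reweighted least squares: ordinary
least squares, then alternating Huber weights
$w_i = \min(1, c\,\hat\sigma/|r_i|)$ with $c = 1.345$ and
$\hat\sigma = 1.4826\,\mathrm{median}|r|$, plus *hard trimming* of the
20% of probes with the largest absolute residuals, to coefficient
convergence. The 20% trim fraction follows the cross-validated value
reported for this class of PBM model; the Huber $\psi$-function is the
conventional choice the trimming is layered on. Bright-spot artifacts —
emulated in the generator as 10-fold multiplicative outliers — are
exactly the contamination this guards against; with plain least squares
the dinucleotide estimates in particular are driven far from truth (the
package's tests assert both directions of this contrast).

### Seed selection guards

Two selection rules sit on top of the trimmed-mean iteration, both
needed because a desk-scale synthetic dataset cannot reproduce the
coverage guarantees of a universal array design, where every 8-mer
appears in dozens of unrelated sequence contexts:

* coefficients are only iterated for oligomers observed in enough probes
  that the trimmed mean actually trims
  ($\lfloor 0.15\,n\rfloor \ge 1$); an untrimmable "trimmed" mean is not
  robust, and letting one-probe oligomers compete for credit injects
  that probe's noise into every estimate;
* the final argmax is restricted to oligomers in at least
  `seedMinSupport` (30) probes and re-resolved within the *sequence
  family* of the raw winner (oligomers alignable to it within a shift of
  3 at $\ge K-3$ matching bases, on either strand): family members with
  less than half the family's maximum support are excluded before the
  final argmax. Sliding-window shadows of a concentrated binding site
  share nearly all their probes with the site and acquire statistically
  indistinguishable — sometimes larger — coefficients; support dominance
  within the family resolves this scale-freely, leaves uniform-coverage
  designs untouched, and cannot transfer the seed to a genuinely
  different motif (which matters for multi-mode fitting).

### Structural refinement

* **Palindromes.** Forward-strand-only and reverse-strand-only PSAMs are
  fitted from the same seed and compared on the relative-affinity scale
  (mean per-column L1 distance, tolerance 0.1). Because site
  orientation on a double-stranded probe is arbitrary, both strand fits
  see signal; for a palindromic factor they converge to the same matrix,
  for an asymmetric one to reverse-complement mirror images. A detected
  palindrome is re-seeded with the best self-complementary K-mer within
  Hamming distance 2 and refit with positions tied,
  $\Delta\Delta G(j, b) = \Delta\Delta G(L-1-j, \mathrm{comp}(b))$
  (mirror-averaging after each block update), halving the free
  parameters; the centre column of an odd-length motif stays untied.
  Tied models give exactly strand-symmetric affinities, which makes the
  forward and reverse view columns of the bias design identical — the
  bias fit therefore ties the strands for symmetric models.
* **Motif length.** The window grows one column per side at a time,
  refitting after each growth, and a growth step is kept iff R² on a
  held-out 10% probe split improves; training R² would grow for any
  nested extension, so held-out data decide. Growth past the probe
  boundary is refused.
* **Poly-G/C strands.** Four or more consecutive guanines interfere with
  probe synthesis on some array designs; a seed containing `CCCC` is
  scored on the forward strand only, one containing `GGGG` on the
  reverse strand only.

### Multiple binding modes

Forward selection: fit one mode; fit a second full model to the
residuals; iteratively re-fit each mode against the intensities minus
the other modes' contributions, blending old and new free energies with
the same step size $\alpha = 0.1$ on the $\Delta\Delta G/RT$ scale; then
a final robust multiple regression of the intensities on the per-mode
affinity sums gives each mode's relative $K_a$ (normalised to the
strongest mode) and a t-test p-value. A candidate is rejected when it
rediscovers an existing mode (same seed, or mean mononucleotide
difference below 0.05), when it explains less than 10% of the residual
variance, when its p-value exceeds 0.01, or when its relative $K_a$
falls below 1% of the primary mode's. The last two guards are both
needed: the t-test alone is anti-conservative because each candidate was
optimised on the very residuals it is tested against, so "significant"
residual-structure modes with relative $K_a$ of $10^{-4}$ to $10^{-1}$
appear routinely on single-mode data, while genuine secondary modes in
our two-mode simulations explain essentially all of the residual
variance.

### Genome scoring

Promoter affinity is the plain sliding-window sum of relative affinities
over all views of the sequence, both strands unless the strand policy
restricts, weighted by relative $K_a$ across modes — the positional-bias
profile is a microarray artifact and deliberately does not enter.
Gene Ontology association ranks genes by total promoter affinity and
applies a two-sided Wilcoxon-Mann-Whitney test per category (exact for
small untied groups, normal approximation with tie correction
otherwise; a one-sided high-affinity alternative is available),
Bonferroni-corrected over the categories tested. ChIP enrichments are
related to model affinities through the single-parameter occupancy curve
$\mathrm{scale}\cdot Pa/(Pa+1)$, fitted by nonlinear least squares from
several starting concentrations; the fit is performed on the raw
enrichment scale (so rescaling the enrichments rescales only `scale`)
and the reported RMSE is computed after normalising enrichments to
maximum 1, making it comparable across datasets. A grouped trimmed-mean
utility (10% default) condenses per-site enrichments per K-mer first.

## The synthetic-data generator

Every inference stage is validated against `simulatePBM()`, which
emulates a universal-PBM-like geometry scaled to desk size and ships its
complete ground truth alongside the data:

* 30-bp random probes, 5,000 by default (large-scale designs have ~40k
  probes of 36 bp; tests use sizes from a few hundred to 5,000 for
  speed — the problem sizes used by each check are stated in its code);
* half the probes carry a planted site: a copy of the true reference
  mutagenised at 15% per position (supplying the single and double
  mutants that pin down the free energies), inserted at a random offset
  and in a random orientation — orientation randomness is what makes
  strand-specific fits meaningful on double-stranded probes;
* a positional-bias ramp rising from 0.2 to 1 away from the substrate
  (flat, end-dip and custom profiles available);
* intensities from the forward model ($\beta_0 = 100$,
  $\beta_1 = 1000$, in fluorescence-like units), Gaussian noise with sd
  equal to 5% of the noiseless signal sd, and an optional fraction of
  10-fold multiplicative bright-spot outliers;
* optionally, a planted dinucleotide dependency: a chosen dinucleotide
  at a chosen position, added to the truth's dinucleotide block and
  planted as a *coordinated double substitution* in 10% of planted
  sites. This design point matters twice over. A pairwise dependency
  expressed only through contexts that single-mutant marginals also see
  is absorbed by the mononucleotide fit (fitted first, by convention),
  so the coordinated carriers must stay a minority of each involved
  base's informative windows; and a dependency buried under two strong
  core substitutions leaves its carrier windows with negligible
  affinity, below what any estimator can resolve against noise. The
  recovery tests therefore plant the dependency between softer motif
  positions and raise the mutagenesis rate so single-mutant windows are
  abundant.

What the generator does **not** emulate: de Bruijn coverage guarantees,
spatial (image-level) artifacts, probe secondary structure, or
cross-array normalisation issues. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to every failure mode
of real arrays.

The GO fixture plants extra reference sites in the promoters of one
annotation category; the seed-discovery and recovery checks use the
planted-site design above.

## Numerical choices and degenerate inputs

* Non-reference mononucleotide free energies initialise at
  $\Delta\Delta G/RT = 1$; starting at 0 would make all windows
  equivalent and the first block regression degenerate.
* A feature whose regression coefficient comes back non-positive is
  assigned the ceiling $\Delta\Delta G/RT = 10$ ("never observed
  bound"); a feature absent from every view is an error naming the
  feature, as is a rank-deficient design (naming the collinear
  columns).
* Convergence tolerances: $10^{-8}$ (relative) for IRLS coefficients,
  $10^{-4}$ for within-phase block cycling, $10^{-6}$ relative for seed
  coefficients (200-iteration cap).
* Ties in trimming are broken by index order; exactly
  $\lfloor 0.2\,n\rfloor$ probes carry zero weight after each robust
  stage.
* A perfect linear fit (all residuals at machine zero) keeps all
  weights at 1 rather than dividing by a zero scale.
* The probe-order invariance of seed discovery and the byte-identical
  reproducibility of model files under a fixed seed are asserted in the
  test suite.

## Limitations

* The additive free-energy model ignores interactions beyond adjacent
  dinucleotides, insertions/deletions within the site, and overlapping
  views competing for protein (views are summed independently, as in
  the intensity model above).
* Seed discovery needs the binding site to be well-supported: on small
  datasets without planted sites (where a specific 8-mer occurs only a
  handful of times), no method of this family can identify the seed
  reliably.
* The dinucleotide convention ties dinucleotide values to the frozen
  mononucleotide scale; dinucleotide effects expressible by the
  mononucleotide marginals are, by construction, reported as
  mononucleotide effects.
* Positional bias is per-view multiplicative only; spatial array
  gradients across the slide are out of scope.

## A worked run

```{r example, eval = FALSE}
spec <- simSpec(nProbes = 2000, rngSeed = 7)
probes <- simulatePBM(spec)
fit <- fitModel(probes, fitConfig(rngSeed = 1))
fit
cor(gammaProfile(positionalBiasOf(fit)),
    attr(probes, "truth")$gamma[[1]])
```

The README shows this example with its printed output; the
`scripts/acceptance.R` script re-derives all headline recovery numbers
from scratch.
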