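---
title: "Attribution methods for patch-token classifiers: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribution methods for patch-token classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchattr)
```

## The problem

Vision transformers classify an image by splitting it into a grid of $d$
square patches (tokens) and attaching a class token whose final embedding
drives the prediction. In computational pathology the images are tiles of
hematoxylin-and-eosin stained whole-slide scans and the prediction is, for
example, *tumor* versus *normal*; a pathologist reviewing such a prediction
needs to know **which patches** the model relied on. Post-hoc attribution
methods answer this with one real score per patch, rendered as a red
(important) to blue (unimportant) heatmap.

This package implements four families of attribution for any classifier that
satisfies a small adapter contract (`classifier_adapter()`: class
probabilities, optionally input-pixel gradients, per-layer attention
matrices, and masked evaluation), together with the insertion/deletion
faithfulness metrics used to compare them, and a synthetic pseudo-histology
generator so that every estimator can be validated against a brute-force
oracle without any external data or trained weights.

## The methods

### Attention rollout

During a forward pass each layer $l = 1,\dots,n$ produces a row-stochastic
attention matrix $A_l \in \mathbb{R}^{(d+1)\times(d+1)}$ (head-averaged;
see below). Interpreting the stacked layers as a layered graph with edge
weights $A_l[i,j]$, the importance of input token $i$ is the total
information flow into the final class token: the sum over all layered paths
of the product of traversed weights, which collapses to the class-token row
of the matrix product

$$\text{rollout}(i) = \left[A_n \cdot A_{n-1} \cdots A_1\right]_{\text{cls},\,i}.$$

`rollout_attribution()` computes the product; `path_flow_oracle()` literally
enumerates the paths (exponential in $n$, guarded to desk scale) and the two
agree to $10^{-10}$ on every random stack in the test suite. Because a
transformer block adds a skip connection around the attention module,
the *residual* variant replaces each $A_l$ by the row-renormalized
$A_l + I$ before the product; with row-stochastic input this equals
$\tfrac12 A_l + \tfrac12 I$. Scores are reported raw; normalization happens
only at rendering.

Two details are not fixed by the usual presentation of the method and are
therefore explicit configuration here: **(1)** multi-head attention is
collapsed by the arithmetic mean over heads (the default throughout the
rollout literature); **(2)** the class-token column is simply dropped from
the reported map after the product.

### Integrated gradients

For a baseline $x'$ (default: the black image) and input $x$, the straight
line $\gamma(t) = x' + t(x - x')$ gives, by the fundamental theorem of
calculus for line integrals,

$$f(x) - f(x') = \sum_i (x_i - x_i') \int_0^1
  \frac{\partial f}{\partial x_i}(\gamma(t))\,dt,$$

and the $i$-th summand is the attribution of component $i$. The integral is
approximated by a Riemann sum with $n$ steps (`ig_config(steps = )`,
default 64); per-pixel attributions are summed over the pixels and channels
of each patch to give the per-patch map. The *completeness gap*
$|\sum_i \phi_i - (f(x) - f(x'))|$ is the built-in diagnostic: it is zero to
machine precision on linear models for **any** $n$ (the integrand is
constant), and shrinks with $n$ on smooth models.

Numerical choices: the midpoint rule is the default (second-order accurate,
so the gap is often already tiny at small $n$); the left rule is available
and is what the step-count convergence checks use, because its $O(1/n)$
error decays monotonically and makes the trend assertion sharp.
The differentiation target is the **pre-softmax logit** of the target class
(softmax saturation makes probability gradients vanish precisely on
confidently classified images, which are the interesting ones); the
probability target remains available via configuration.

### RISE

RISE treats the classifier as a black box: patch $i$ is important when the
class score stays high under random masking of the other patches,

$$\text{rise}(i) = \mathbb{E}\left[f_y(x \odot M) \mid M_i = 1\right],$$

estimated by Monte Carlo as $\sum_m f_y(x \odot m)\, m_i / \sum_m m_i$. The
empirical inclusion count in the denominator (rather than the theoretical
$\mathbb{E}[M_i]$) keeps the estimator an unbiased conditional mean even
when inclusion counts fluctuate. Two mask laws are provided: independent
Bernoulli($p$) entries (default $p = 0.5$) and uniform-cardinality masks
($k$ uniform on $\{0..d\}$, then a uniform $k$-subset). Masks are
patch-aligned binary vectors at token resolution — no low-resolution
upsampling as in the original formulation for CNNs, since the classifier's
own token grid is the natural masking unit. Evaluation is chunked
(`masks_per_chunk`) purely for throughput; results are bitwise independent
of the chunking. `exact_rise()` enumerates all $2^d$ masks (guarded at
$d \le 14$) and is the oracle: at $d = 8$ and 50,000 masks the Monte-Carlo
estimate is required to land within three of its own standard errors.

### Shapley values

The removal game of an image is $v_{xy}(m) = f_y(x \odot m) - f_y(0)$, with
the baseline prediction subtracted so $v(0) = 0$. The Shapley value

$$\phi_i = \frac{1}{d} \sum_{m\,:\,m_i = 0}
  \binom{d-1}{\mathbf{1}^\top m}^{-1} \left(v(m + e_i) - v(m)\right)$$

is the unique allocation satisfying efficiency
($\sum_i \phi_i = v(\mathbf 1)$), symmetry, and the null-player axiom.
`exact_shapley()` enumerates it directly ($2^d$ game queries, guarded at
$d \le 14$). Beyond that scale the package uses the weighted-least-squares
characterization: minimize
$\mathbb{E}_{p_{sh}(m)}[(v(m) - m^\top\phi)^2]$ subject to
$\mathbf 1^\top \phi = v(\mathbf 1)$, where the Shapley kernel assigns mask
$m$ weight proportional to
$(\mathbf 1^\top m - 1)!\,(d - \mathbf 1^\top m - 1)!$ on
$0 < \mathbf 1^\top m < d$ (cardinality marginal $\propto 1/(k(d-k))$).
`regression_shapley()` solves the constrained problem in closed form via the
bordered KKT system — with the exhaustive admissible design and exact kernel
weights this reproduces the enumeration definition to $10^{-6}$ and better,
which is the module's central oracle test; with masks sampled from the
kernel it is the Monte-Carlo estimator. Any candidate solution is projected
onto the constraint by **additive efficient normalization**,
$\hat\phi_i = \phi_i + (v(\mathbf 1) - \mathbf 1^\top\phi)/d$, an idempotent
affine projection.

Two more pieces mirror the full-scale recipe at toy scale. First, masked
inputs are off-distribution for classifiers never trained on them, so a
*surrogate* model can be fitted to match the classifier under the masking
law $p(m) = [\binom{d}{\mathbf 1^\top m}(d+1)]^{-1}$ (uniform cardinality,
then uniform subset) by minimizing the KL divergence
`surrogate_objective()`; the surrogate then replaces the classifier inside
the game. Second, `train_explainer()` fits an amortized *explainer* that
emits a Shapley map in one forward pass, minimizing the kernel-weighted
squared error with the efficiency constraint enforced **by construction**:
every forward pass ends with the additive efficient normalization, during
training and at inference. The package's explainer is deliberately minimal
— per-patch affine in a per-patch feature, trained with Adam — because the
point is the objective and the projection, not network architecture; on
additive games it must recover the closed-form Shapley values on held-out
games to within 5% of the score range.

## Faithfulness metrics

Given a ranking from `rank_patches()` (descending scores, ties broken by
ascending patch index), **insertion** starts from the fully masked image and
reveals patches in rank order, recording $f_y$ at every step; **deletion**
starts from the full image and removes them. Both curves have exactly
$d + 1$ points; the score is the area under the curve by the trapezoid rule
over the patch *fraction* $\#p/d \in [0,1]$, so AUCs are comparable across
grid sizes. Higher insertion and lower deletion are better; the random
baseline is the mean over uniformly random rankings. Aggregation follows the
two conventions used for slide-level reporting: the grand mean over all
patch AUCs, and the mean of per-slide means (slides weighted equally even
when they contribute different patch counts — the populations are explicitly
not i.i.d.). Method comparison uses two-sided Welch (unequal-variance)
t-tests on the AUC populations, with no multiplicity correction by default.

Metric evaluation reuses the same adapter that produced the attribution (a
surrogate may be substituted for both). Useful exact identities the suite
asserts: insertion point 0 equals deletion point $d$ bitwise (fully masked)
and insertion point $d$ equals deletion point 0 (full image); and for an
additive classifier with a monotone link, the true weight ranking dominates
every random ranking on both metrics (a rearrangement argument).

## Preprocessing

Tissue is separated from the near-grey slide background by the
*colorization value* $c(r,g,b) = |r-m| + |g-m| + |b-m|$ with
$m = (r+g+b)/3$: zero exactly on grey pixels, large on chromatic (stained)
tissue, invariant under channel permutation and grey shifts. The threshold
is either a global constant (`fixed`, exactly reproducible on flat synthetic
textures) or a local-mean threshold (`adaptive`: integral-image box mean
with an odd window, replicate padding, plus an offset). The adaptive
window/offset defaults (31 px, 0.02) are package defaults, not literature
values — the thresholding reference the pipeline descends from states no
parameters. Patch extraction tiles the image non-overlapping row-major at a
fixed size (256 px default for slide-scale input), drops partial edge tiles,
and keeps a tile when its tissue fraction reaches `min_tissue_fraction`
(default 0.1; the acceptance rule for partially filled tiles is likewise a
package choice).

## The synthetic generator and the reference models

`generate_pseudo_slide()` emulates the *chromatic* structure of H&E tiles
and nothing else: flat per-class color means (tumor purple-dominant, normal
tissue pink-dominant, background near-grey) plus i.i.d. Gaussian pixel noise,
with known per-patch labels. The palette guarantees strict separation of
tissue from background by colorization value at zero noise, and the default
noise scale (0.02) keeps that separation with margin. What it deliberately
does **not** model: nuclear morphology, stain variation, spatial texture
correlation, magnification effects. Passing tests on this generator
therefore demonstrates estimator correctness (oracle equivalence, planted
signal recovery), not robustness to real histological variability.

Three reference models exercise the adapter contract:

* `make_linear_patch_scorer()` — score
  $s = \sum_i w_i \cdot \text{mean-intensity}(\text{patch } i)$ through an
  identity or sigmoid link. Under the identity link the induced game is
  additive, so its exact Shapley values are $w_i \cdot$ intensity — the
  package's most important closed-form oracle. (With the identity link the
  "probabilities" $(1-s, s)$ can leave $[0,1]$; it is an analytic test
  device, not a classifier.)
* `make_tiny_vit()` — a genuinely random small transformer (linear patch
  embedding, class token, positional embeddings, multi-head softmax
  attention with residuals, tanh MLP with residuals, linear head) with
  **exact reverse-mode input gradients** written out by hand and verified
  against central finite differences at $10^{-3}$ relative tolerance. Layer
  normalization is omitted: random desk-scale initializations keep
  activations bounded, and the omission keeps the backward pass short
  enough to audit line by line.
* `make_color_attentive_vit()` — a one-layer, one-head transformer whose
  weights are set analytically so the class token attends to patches in
  proportion to $\exp(\tau \cdot \text{purpleness})$ and the class-2 logit
  reads out the attention-weighted purpleness
  ($\text{purpleness} = (r+b)/2 - g$ of the mean patch color). Unlike a
  randomly initialized transformer it genuinely prefers the planted tumor
  texture, which makes it the demonstration classifier for end-to-end runs:
  all five method families (attention-, gradient-, and removal-based, plus
  the random baseline) produce meaningful cells against one model.

## Numerical conventions and degenerate cases

* Mask fill value 0 (black) everywhere by default, matching the black-image
  baseline of both the integrated-gradients path and the removal game;
  configurable per call.
* All-ones masks short-circuit to the original pixels, so masked and
  unmasked predictions are bit-identical, not merely close.
* Enumeration guards: $2^d$ paths at $d \le 14$; path enumeration for
  rollout guarded by total path count. Exceeding a guard is an error, never
  a silent approximation.
* Ties in attribution scores are broken by ascending patch index; constant
  maps therefore rank patches in index order, and render at the colormap
  midpoint (the min-max normalization of a constant map is defined as 0.5).
* A RISE patch never included in any mask has an undefined conditional mean:
  an error by default, score 0 with a warning if the fallback is enabled.
* Probability vectors are validated to sum to 1 within $10^{-6}$, attention
  rows within $10^{-5}$, on every adapter call.
* Every stochastic step takes an integer seed; the benchmark derives one
  seed per (slide, image, method) cell from the master seed, so full runs
  are reproducible and cells are independent of method ordering.

## Problem sizes

The test and acceptance workloads run at desk scale, chosen so every
estimator can be compared against exhaustive enumeration: games and RISE
oracles at $d = 8$, rollout oracles at $d \le 6$ and $\le 3$ layers,
mask-law enumeration at $d = 12$, Monte-Carlo checks at 20,000–50,000
masks, the planted-signal benchmark on $3 \times 3$ grids of $8$-px patches,
and the explainer on $d = 6$ additive games. These sizes are the package's
validation conditions; the estimators themselves scale to realistic token
counts (e.g. $14 \times 14$ grids) through the regression and explainer
paths, which is exactly the regime the enumeration guards exclude.

## Known limitations

* The amortized explainer is a linear-in-features toy; it demonstrates the
  objective, the mask law, and the projection, not representation learning.
* The surrogate is available as an adapter swap (any fitted
  `classifier_adapter` can replace the original in games and metrics), but
  no full surrogate training loop is provided — only its objective and mask
  law, which are tested.
* The preprocessing front end reads flat PNG images; pyramidal whole-slide
  containers and magnification handling are out of scope, and inputs are
  assumed to be at working resolution.
* Insertion/deletion inherit the usual caveats of removal-based evaluation:
  they presuppose that removing information is meaningful to the model,
  ignore inter-patch correlation, and depend on the classifier's (or
  surrogate's) robustness to masked inputs.
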