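---
title: "Interval type-2 fuzzy neural networks: model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval type-2 fuzzy neural networks: model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(it2fnn)
```

## The problem

Screening problems such as cardiotocography (CTG) interpretation ask a
classifier to map a vector of continuous clinical summaries — fetal heart
rate baseline, acceleration and deceleration rates, variability measures,
FHR-histogram statistics — onto a small set of ordered health states
(Normal / Suspect / Pathological). Expert readers disagree about where the
boundaries of a "normal" interval for each symptom lie, so a model whose
membership boundaries are themselves uncertain is a natural fit. `it2fnn`
implements a fuzzy neural network whose rule antecedents are *interval
type-2* Gaussian sets: each rule's membership function for each input has an
uncertain center, and inference propagates a lower and an upper membership
bound instead of a single grade.

## The model

A network with $m$ inputs, $n$ rules and $p$ outputs holds, for rule $j$ and
input $i$, a Gaussian membership function with width $\sigma_{ij}$ and a
center known only to lie in $[c^1_{ij}, c^2_{ij}]$:

$$\mu_{ij}(x) = \exp\!\left(-\frac{(x - c_{ij})^2}{\sigma_{ij}^2}\right),
\qquad c_{ij} \in [c^1_{ij}, c^2_{ij}].$$

Note the exponent uses $\sigma^2$, not $2\sigma^2$; the package follows this
convention throughout, so widths are not interchangeable with ordinary
Gaussian standard deviations. Under the standard uncertain-mean
construction, the envelope of all such Gaussians is bounded above by a
function that equals 1 on $[c^1, c^2]$ and decays through the nearer center
outside it, and below by the pointwise minimum of the two center Gaussians.
These are the `lower` and `upper` values returned by
`membership_interval()`; the region between them is the footprint of
uncertainty.

Rule firing conjoins the per-input bounds with the product t-norm,

$$\underline{f}_j = \prod_i \underline{\mu}_{ij}(x_i), \qquad
  \bar{f}_j = \prod_i \bar{\mu}_{ij}(x_i),$$

(a `tnorm = "min"` variant is available; product is the default because the
rule-strength formula is a product, and it is also the differentiable
choice). Each rule carries a linear consequent without bias,
$y_j = \sum_i x_i v_{ij}$, and the interval result is reduced to a crisp
output vector by a fixed blend of the lower and upper weighted means:

$$u_k = p\,\frac{\sum_j \underline{f}_j y_j w_{jk}}{\sum_j \underline{f}_j}
      + q\,\frac{\sum_j \bar{f}_j y_j w_{jk}}{\sum_j \bar{f}_j},
  \qquad p = q = \tfrac12,\; p + q = 1.$$

This closed form replaces iterative Karnik–Mendel type reduction; it is
cheap, differentiable, and adequate when $p$ and $q$ are treated as ordinary
(fixed or trainable) parameters. The package keeps $p = q = 0.5$ fixed
during training by default, because the design procedure's update step names
only the antecedent centers and widths and the consequent weights; setting
`train_pq = TRUE` in `train_config()` makes $p$ trainable under the
constraint $q = 1 - p$ (projected to $[0,1]$).

Classification uses one-hot targets: class $c$ of $p$ becomes the unit
vector $e_c$, and predictions take the argmax of $u$, with ties broken
toward the lowest class index so the decision rule is deterministic.

## Training

The per-sample loss is the sum of squared output deviations
$E = \sum_k (u^d_k - u_k)^2$ (no square root — the square root enters only
in the *reported* RMSE, defined as $\sqrt{\text{mean}}$ of squared
deviations over samples and outputs). Gradients of $E$ through the piecewise
membership envelopes are computed analytically in compiled code; on the
upper envelope the active branch's derivative is used, and at a branch
boundary the interior (value-1) branch applies, whose derivative is zero.
The test suite verifies every partial derivative against central finite
differences.

One training run proceeds as follows. Per epoch, each of the $K = 10$ folds
in turn is held out; the model is updated sample by sample on the other
$K-1$ folds in a freshly shuffled order. A sample triggers an update only
when its largest absolute output residual exceeds the threshold
$\Delta$ (default $10^{-4}$ — "an acceptably small error"); updates use
momentum (default 0.9) with learning rate (default 0.05) shared across all
parameters. After each update the parameter invariants are repaired: widths
are floored at $10^{-4}$ and an inverted center pair is swapped. The
held-out fold's RMSE is recorded as validation; after the full epoch the
epoch-mean training RMSE drives a bold-driver learning-rate adaptation
(×1.05 after improvement, ×0.7 after deterioration, clamped to
$[10^{-6}, 1]$) and the parameters are checkpointed whenever that epoch-mean
training RMSE is the best seen so far. The checkpointed model is returned.

Two deliberate readings of the procedure deserve a note:

* **Rate adaptation granularity.** The adaptation is applied once per epoch
  on the epoch-mean training RMSE rather than after every fold. Per-fold
  comparisons contrast RMSEs computed on different training subsets; that
  subset noise makes the asymmetric bold-driver rule (log 1.05 < |log 0.7|)
  shrink the rate geometrically regardless of progress, which we observed as
  premature convergence. Epoch-level comparison contrasts like with like.
* **Checkpoint criterion.** Checkpointing follows the training RMSE, exactly
  as the procedure states, even though validation-based selection is more
  orthodox; `checkpoint = "validation"` switches to the latter.

Fold assignment is unstratified by default (the procedure divides the data
into ten equal groups without mention of stratification); because the CTG
classes are imbalanced, `stratified = TRUE` deals each class round-robin
across folds, preserving per-class proportions within one sample.

Training is bit-reproducible: a single integer seed drives initialization
(centers uniform on $[0,1]$ with uncertain-mean half-width
$h \sim U(0.01, 0.1)$, widths $\sigma \sim U(0.05, 0.5)$, consequent weights
$U(-0.5, 0.5)$), fold assignment, and every per-epoch shuffle.

## Preprocessing

Features are min–max scaled to $[0,1]$. The scaler is fitted once on the
full dataset before cross-validation, exactly as the modelled procedure does
it; this leaks fold information through the per-feature extrema, which is
documented here deliberately — `it2fnn_crossval(scale = "per_fold")`
provides the leakage-free alternative (scaler and model refitted per outer
fold, held-out metrics averaged). A constant feature scales to 0 with a
warning.

Missing cells are filled by a class-conditional linear-interpolation
imputer. For each affected feature, the observed range $[x_{min}, x_{max}]$
and the range of co-occurring class codes $[y_1, y_2]$ are divided into
$nc - 1$ equal steps, giving paired centers
$x_{ck} = x_{min} + (k-1)\Delta x$ and $y_{ck} = y_1 + (k-1)\Delta y$; a
missing cell in a row of class $y_{ck}$ receives the paired $x_{ck}$. The
construction as stated is written for a linearly *increasing*
feature–class relationship; to make the decreasing case operational, the
package estimates the direction from the sign of the correlation between
observed values and class codes, and a negative sign reverses the
class-to-center mapping. Class centers $y_{ck}$ may be non-integer when the
observed class range does not span all classes; lookups then use the nearest
center. The imputer is idempotent, never alters observed cells, and restores
data generated exactly on its own linear model bit-for-bit — both properties
are under test.

## Synthetic data

Real CTG tables cannot ship with the package, so three generators stand in:

* `generate_ctg_like()` draws each of the 21 features from a normal with the
  packaged published mean and standard deviation, truncated to the published
  $[\min, \max]$ by rejection (clipping fallback after 50 rounds). Class
  labels are drawn with proportions $(0.78, 0.14, 0.08)$, chosen to be
  consistent with the published label mean of 1.304 for the three ordered
  classes; the true per-class counts of the source table are not published.
  Eight clinically salient features (baseline value, accelerations, uterine
  contractions, prolonged decelerations, the three abnormal-variability
  summaries, histogram variance) receive class-dependent mean shifts of
  $(-0.19, +0.25, +0.5)$ standard deviations for classes 1–3; the weights
  solve $\sum_c \pi_c \, d_c = 0$ under the default proportions, so the
  *marginal* moments stay on the published targets while the classes remain
  (weakly) learnable. What this generator does **not** emulate: the strong
  skew and zero-inflation of the event-rate features (for
  `severe_decelerations` the published mean/std/min/max are mutually
  inconsistent with *any* distribution on the range, up to printed rounding,
  by the Bhatia–Davis variance bound — no generator can match them exactly),
  inter-feature correlations, and the deterministic relations between the 11
  sensor features and the 10 derived ones. Moment tests therefore compare
  sample moments against the generator's own analytic truncated-normal
  mixture moments, plus the published mean for the mildly truncated FHR
  baseline, where truncation bias is negligible.
* `generate_blobs()` produces isotropic Gaussian clusters (unit sd) with
  centers a chosen distance apart; separation 8 with three classes in two
  dimensions is the "well-separated" learnability testbed, where a
  nearest-center oracle scores ≈ 1.
* `generate_linear_response()` places a single feature exactly on the
  imputer's class centers, increasing or decreasing, for exact-recovery
  tests.

Passing tests on these generators demonstrate the mechanics of the method —
gradient correctness, convergence on separable data, capacity trends,
robustness of training to impute-recovered cells — not clinical performance
on real CTG recordings.

## Numerical choices

* The type-reduced weighted means are scale-invariant in the firing
  strengths, and with many inputs the product t-norm routinely drives the
  firing sums to $10^{-40}$–$10^{-80}$ — small, but exactly representable,
  and the quotients remain accurate. The additive $10^{-12}$ guard is
  therefore applied *only* when a denominator underflows to numerical zero
  (with a diagnostic message); guarding earlier, e.g. at $10^{-12}$, would
  silently attenuate valid outputs by many orders of magnitude. Because the
  guard never fires in the ordinary regime, the degenerate type-1
  equivalence holds to $10^{-12}$.
* In the small-firing regime the antecedent gradients carry a
  $1/\sigma^2$-scale factor that can exceed the consequent gradients by two
  or more orders of magnitude; the SGD loop rescales any per-sample gradient
  whose sup-norm exceeds 10 (standard norm clipping) and skips the rare
  sample whose gradient is not finite. The analytic gradients exposed by
  `it2fnn_gradients()` are raw (unclipped), which is what the
  finite-difference checks verify.
* The default learning rate (0.05) suits low-dimensional problems such as
  the blob testbed. With $m = 21$ inputs the rule outputs
  $y_j = \sum_i x_i v_{ij}$ and their gradients are roughly an order of
  magnitude larger, and 0.05 overshoots; the packaged CTG-scale experiments
  therefore run at `lr = 0.002`, chosen for stability (convergent at 0.002
  and 0.01, divergent at 0.05), with the bold driver growing it as training
  progresses.
* Lower-membership ties at the interval midpoint resolve to the $c^1$
  branch; upper-membership boundary points resolve to the interior branch
  (derivative 0). Both choices are measure-zero and verified against finite
  differences away from the boundaries.
* Model JSON checkpoints print floats with 17 significant digits, so
  save→load→forward is bit-exact and identical models save byte-identically.
* Problem sizes used by the packaged checks are the package's own choices
  balancing statistical resolution against desk-scale runtimes: 2126-row
  tables (the published table size) with 5 training epochs for the
  capacity comparison (21 vs 63 rules, 5 seeds), 3 epochs and 10 seeds for
  the erase-150 robustness comparison, full procedure defaults (1000
  epochs, 10 folds, 21 rules) for the 300-sample blob learnability run.

## Known limitations

* The closed-form $p/q$ type reduction is an approximation to exact interval
  type reduction; no Karnik–Mendel variant is provided.
* Consequents are linear without bias; inputs identically 0 always produce
  output 0 regardless of training.
* Accuracy on the synthetic CTG-like table is limited by the deliberately
  weak class separation of the generator and says nothing about accuracy on
  real CTG data.
* The imputer assumes a monotone (linear) feature–class relationship and a
  valid class label for every row holding a missing cell; rows with missing
  labels are rejected rather than guessed.
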