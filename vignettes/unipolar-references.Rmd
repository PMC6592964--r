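---
title: "Unipolar EEG references: the operator family, REST, and estimators of the potential at infinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unipolar EEG references: the operator family, REST, and estimators of the potential at infinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urefs)
```

## The reference problem

EEG amplifiers measure potential differences, never potentials.  The
quantity every analysis would like to have is the vector of scalp
potentials $\varphi \in \mathbb{R}^{N_c}$ referenced at infinity — an
idealized zero-potential point — related to the equivalent neural source
currents $j \in \mathbb{R}^{N_s}$ through the volume-conduction forward
model

$$\varphi = K_\infty\, j,$$

with $K_\infty$ the $N_c \times N_s$ lead field referenced at infinity.
What is actually observed is a referenced transformation of $\varphi$ plus
sensor noise,

$$x = T_o(\varphi + \varepsilon) = T_o \varphi + \varepsilon_o, \qquad
  \Sigma_{\varepsilon_o \varepsilon_o} = \sigma^2 T_o T_o^\top$$

(the referencing acts on the noise too).  Estimating $\varphi$ from $x$ is
an underdetermined linear inverse problem: every reference transform is
rank deficient, and what was lost can only be restored through prior
information.

## The unipolar family

A *unipolar reference* (UR) subtracts one common signal — a linear
combination $f_r^\top \varphi$ — from all channels:

$$T_r = I_{N_c} - \mathbf{1} f_r^\top, \qquad f_r^\top \mathbf{1} = 1.$$

The package constructs the four standard members with `ur_weights()`:

| kind | weights $f_r$ | meaning |
|------|----------------|---------|
| RR   | indicator $e_k$ | physical recording reference (Cz, Fz, ...) |
| LM   | $0.5$ at each mastoid | linked mastoids / earlobes |
| AR   | $\mathbf{1}/N_c$ | average reference |
| REST | $K_\infty^{+\top} K_\infty^{+} \mathbf{1} \,/\, (\mathbf{1}^\top K_\infty^{+\top} K_\infty^{+} \mathbf{1})$ | reference standardization |

Three properties hold for every member (and are enforced as tests):

* **No memory**: $T_{r1} T_{r2} = T_{r1}$ whenever $f_{r1}^\top\mathbf{1}=1$.
  Re-referencing replaces any previous UR completely; applying URs
  repeatedly accumulates nothing.  The guarantee requires the *previous*
  transform to be a UR — `apply_reference()` warns when the provenance of
  the data is unknown, because transforming non-UR data (bipolar
  derivations, Laplacians) is destructive and undetectable after the fact.
* **Rank deficient by one**: $\mathrm{rk}(T_r) = N_c - 1$.  Exactly one
  dimension — the common offset — is unobservable under any UR.
* **Projector centering**: $T_r^+ T_r = T_{AR}$.  The orthogonal projector
  onto the row space of any UR is the centering (average-reference)
  matrix, which is why minimum-norm estimation under any embedded UR lands
  on AR (below).

## REST is itself a unipolar reference

REST maps referenced data through the equivalent sources:
$\hat\varphi = K_\infty K_r^+ v_r$ with $K_r = T_r K_\infty$.  The
standardization matrix $R_r = K_\infty K_r^+$ depends on the reference
embedded in the data, but the composed operator $R_r T_r$ does not: for a
full-row-rank lead field it collapses, via a rank-one pseudoinverse
modification identity, to

$$T_{REST} = I - \mathbf{1}\,
  \frac{\mathbf{1}^\top K_\infty^{+\top} K_\infty^{+}}
       {\mathbf{1}^\top K_\infty^{+\top} K_\infty^{+}\mathbf{1}},$$

a member of the family.  `rest_operator()` implements both routes
(`"composed"` and `"unipolar"`) independently, and the test suite checks
their agreement for every prior reference on random and spherical lead
fields — this route equivalence is the central structural fact the package
is organized around.  Two corollaries worth noting:

* With $K_\infty = I$ (no volume-conduction information) the REST weights
  reduce to $\mathbf{1}/N_c$: REST degenerates to AR.
* The REST weights minimize $f^\top K_\infty K_\infty^\top f$ subject to
  $f^\top \mathbf{1} = 1$: among all unipolar references, REST picks the
  reference signal with the smallest variance under IID sources.  This is
  the precise sense in which its prior is "more informative" than AR's,
  and it is what makes the Monte-Carlo recovery comparison below come out
  in REST's favor.

On noise-free model-consistent data the REST residual is exactly rank one,
$\hat\varphi - \varphi = -\mathbf{1}(f_{REST}^\top \varphi)$: the
unobservable offset is the *only* error.

## Estimators: BLUE, MLE, MAP

Because $T_r$ is rank deficient by one, one row of the model is redundant;
`reduce_model()` discards it (the physical reference row for RR — it is
identically zero — either mastoid for LM, the last row otherwise; the
estimators are invariant to any admissible choice, which is asserted in
tests).  On the reduced full-row-rank model:

* `blue_ar()` solves the constrained least-squares problem under the
  zero-sum constraint $\mathbf{1}^\top\varphi = 0$ (the discrete version
  of the vanishing surface integral on a layered spherical conductor).
  Both the general constrained formula and its closed-form simplification
  $T_{AR} T_{r-}^+ v_{r-}$ are implemented; they agree to $10^{-9}$ and
  the output has exactly zero column sums.  With negligible noise the
  estimator *is* the average reference.
* `mle_rest()` replaces the linear constraint by the forward model: the
  minimum-source-norm estimator
  $K_\infty K_{r-}^\top (K_{r-}K_{r-}^\top + \lambda T_{r-}T_{r-}^\top)^{-1} v_{r-}$,
  with an independent SVD route (regressing on the rotated sources
  $\beta = W^\top j$, whose minimum Euclidean norm equals that of $j$
  under an IID source prior) used as a cross-check.  At $\lambda = 0$ this
  is classical REST.
* `map_estimate()` is the general Gaussian MAP solution
  $\Sigma T_o^\top (T_o \Sigma T_o^\top + \sigma^2 T_o T_o^\top)^+ x$ for
  any reference transform $T_o$, unipolar or not.  The prior covariance
  $\Sigma$ decides everything: $\alpha^2 I$ (ignore volume conduction)
  reproduces AR in the noiseless limit, for *every* embedded UR;
  $\alpha^2 K_\infty K_\infty^\top$ (IID sources) reproduces REST, and for
  $\sigma^2 > 0$ coincides with the rREST operator.

Only the ratio $\lambda = \sigma^2/\alpha^2$ is identifiable — it is the
single regularization parameter exposed everywhere.  The $\sigma^2 = 0$
limits are explicit pseudoinverse code paths, not numerical limits,
because the underlying statements are algebraic identities (and
$T_o T_o^\top$ is genuinely singular for URs, so a plain inverse would be
wrong).  A note on notation: the source covariance appears in the rREST
literature under two symbols ($\Sigma_{jj}$, $\Sigma_{ss}$); the package
treats them as the same IID equivalent-source covariance $\alpha^2 I$.
The norms in the constrained problems are Euclidean: with an orthonormal
rotation and an IID prior, the Mahalanobis and Euclidean minimum-norm
solutions coincide, so nothing more general is needed.

## rREST and the GCV choice

`rrest_operator()` implements
$K_\infty K_o^\top (K_o K_o^\top + \lambda T_o T_o^\top)^+$ with
$K_o = T_o K_\infty$; `select_lambda_gcv()` picks $\lambda$ by generalized
cross-validation.  One subtlety dictated the design: on the full
$N_c$-channel system, UR-referenced data — noise included — lies entirely
inside the range of $K_o$, so the ridge fit can reproduce the data exactly
as $\lambda \to 0$ and the naive GCV score vanishes there *for any noise
level*; the criterion would always select no regularization.  GCV is
therefore evaluated on the reduced full-row-rank system (the same
reduction the MLE uses), where it has its classical behavior: with
$A(\lambda) = K_m K_m^\top (K_m K_m^\top + \lambda T_m T_m^\top)^{-1}$,

$$\mathrm{GCV}(\lambda) =
  (N_c - 1)\,\overline{\lVert (I - A)v_m \rVert^2} \,/\,
  \mathrm{tr}(I - A)^2 .$$

On noiseless model-consistent data the curve is flat near zero (a 0/0
limit) and the selected $\lambda$ sits in that flat basin, so the estimate
coincides with classical REST for practical purposes; noise moves the
minimum strictly into the grid.  One shared $\lambda$ is selected per
recording — the estimator is one operator, not one per sample.  The
default grid is 40 log-spaced points over $[10^{-12}, 10^{2}]$ times
$\mathrm{tr}(K_o K_o^\top)/N_c$, which makes the search invariant to the
scaling of the lead field.

## The spherical forward model

`spherical_leadfield()` implements the classical three-concentric-sphere
analytic model (brain, skull, scalp; insulating exterior) by spherical
harmonic series.  Defaults — radii 0.087/0.092/0.100 m, conductivities
0.33/0.0042/0.33 S/m — are the standard literature values for the
three-shell head.  Numerical notes:

* Sensors are projected radially onto the scalp sphere before evaluation
  (digitized positions rarely sit exactly on a sphere); sources must be
  strictly inside the brain shell.
* The per-degree interface conditions are solved as a small linear system
  with row/column equilibration; without it the mix of $\rho^{n}$ and
  $\rho^{-(n+2)}$ terms is numerically singular beyond degree ~100.
* The series for each sensor–source pair is truncated when the relative
  term drops below $10^{-10}$, and errors (rather than truncating
  silently) if 200 terms do not suffice — which only happens for sources
  essentially touching the skull.
* The implementation is validated against the series-free closed-form
  homogeneous-sphere solution (`sphere_potential_homogeneous()`): with all
  conductivities equal, the three-shell series must reproduce it, and does
  to better than $10^{-10}$ relative; a central dipole reproduces the
  $3\,p\cdot\hat r_e / (4\pi\sigma R^2)$ limit.
* Gains are expressed in µV per nA·m.  The absolute scale cancels in every
  REST-type quantity (all are ratios in $K_\infty$), so this choice only
  keeps operator entries at order one.

Source layouts come from `source_grid()`: a deterministic Fibonacci-sphere
shell at a fraction (default 0.8) of the brain radius, radially oriented
by default — the minimal faithful stand-in for the distributed
equivalent-source layer, which is far denser than the electrode array
($N_s \gg N_c$) and orientation-agnostic.  `"free"` orientations (three
columns per location) are available when needed.

## Interpolation of missing channels

Because $K_\infty$ carries a row for every montage channel while the
estimator only consumes the observed rows, evaluating the rREST estimate
through the *full* lead field reconstructs channels that were never
observed — the missing physical-reference channel, or rejected bad
channels.  `interpolate_channels()` accepts both provenances: data under a
UR over the observed subset, and the "reduced form" in which the observed
rows are what remains of a full-montage unipolar recording.  For a single
deleted channel on noise-free model-consistent data the reconstruction
reproduces the full-montage REST estimate to numerical precision (the row
spaces coincide); each *additional* deleted channel costs one dimension of
the equivalent-source projector, so multi-channel recovery is
approximate.  Observed channels are returned with the estimator's own
smoothing and nothing else.  Missing channels must exist in the montage:
no geometric extrapolation is attempted.  Outputs are infinity-referenced
estimates; any desired re-referencing is left to the caller.

## The simulator, and what passing tests do not show

`simulate_recording()` draws IID Gaussian equivalent sources
($j \sim N(0, \alpha^2 I)$), propagates them through the lead field, adds
IID Gaussian sensor noise and applies the reference — exactly the
generative model the estimators assume, with a per-stream seed expansion
so that switching noise on never changes the source draw.  This is
deliberate: the test suite checks *algebraic identities and estimator
consistency under the model's own assumptions*.  Real EEG has temporally
correlated, oscillatory, non-Gaussian sources, artifacts, and a head that
is not three concentric spheres; the Monte-Carlo results here (REST
recovering better than AR, GCV-tuned rREST beating plain REST at low SNR)
quantify the behavior of the estimators under the stated model, not
clinical performance.  `recovery_experiment()` makes those comparisons
reproducible: with the spherical 19-channel model and 300 sources, the
mean relative recovery error of REST is consistently below that of AR
over 100 seeded noise-free trials, and the two coincide trial-by-trial
when $K_\infty = I$.

## Numerical conventions

* All pseudoinverses and rank decisions share one SVD cutoff,
  $\max(\dim) \cdot \varepsilon \cdot \sigma_{\max}$ (`pinv()`,
  `mat_rank()`), so "rank" means the same thing everywhere.
* Weight vectors must sum to one: construction enforces $10^{-9}$
  (user-supplied vectors carry file rounding); generated family members
  satisfy it to $10^{-12}$.
* Channel order is montage order throughout; nothing is reordered
  silently.
* Validation problem sizes: 19-channel 10–20 montage, 300 or 500 sources,
  20–50 samples per recording, 50–100 Monte-Carlo trials — large enough
  for the spherical model to be generic, small enough that the whole suite
  runs in seconds.

## Limitations

* Head models beyond concentric spheres (BEM/FEM, population-average lead
  fields) are out of scope; the lead field reader accepts externally
  computed gain matrices for those workflows.
* The equivalent-source estimate $\hat j = K_r^+ v_r$ is an intermediate
  quantity only; nothing here is source localization.
* Non-IID source priors are not implemented; the MAP machinery accepts
  only the two covariances described above.
* Whether data carries a unipolar reference cannot be detected from the
  data itself; the package tracks provenance through reference tags and
  warns when it is unknown, but cannot protect against mislabeled inputs.
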