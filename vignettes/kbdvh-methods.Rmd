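---
title: "Methods: conditional-KDE DVH prediction in kbdvh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional-KDE DVH prediction in kbdvh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`kbdvh` treats the dose an OAR voxel receives as explained by a single
geometric covariate: the signed minimal Euclidean distance $t$ from the
voxel center to the planning target volume, negative inside the target.
The training cohort supplies paired samples $(t_i, x_i)$ per organ class,
pooled across plans, from which a Gaussian product-kernel estimate of the
conditional dose density is formed:

$$p(x \mid t) = \frac{\sum_i K_{h_x}(x - x_i)\, K_{h_t}(t - t_i)}
                     {\sum_i K_{h_t}(t - t_i)}.$$

A new patient's predicted dose density marginalizes this conditional over
the empirical distribution of the patient's own OAR voxel distances,
$p_D(x) = \frac{1}{M}\sum_j p(x \mid t_j)$, and the cumulative DVH is
$\mathrm{DVH}(D) = 1 - \int_0^D p_D(x)\,dx$.

The approach assumes (i) dose falls off with distance from the target in a
way that is consistent across plans of one protocol, (ii) inter-plan
differences beyond that are noise rather than systematic geometry effects
(no beam-angle, volume, or prescription covariates), and (iii) the training
cohort is of uniformly high quality, since the prediction is a benchmark of
what *comparable* plans achieve, not of what is physically optimal.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `dose_bin_gy` ($\Delta x$) | Gy | 0.1 | makes Vd discretization error negligible against clinically reported RMSEs |
| dose-domain bound | Gy | $1.1\,\max(x_i)$, rounded up to $\Delta x$ | 10% headroom keeps reflected-kernel tail mass off the axis end |
| bandwidths $h_t, h_x$ | mm, Gy | $\hat\sigma_k\, n^{-1/6}$ | the Gaussian-reference rule minimizing asymptotic MISE for a 2-D product kernel; declared and exactly testable. `bandwidth_method: lscv` switches to least-squares cross-validation for clearly non-Gaussian data |
| `max_samples_per_structure` | voxels | 20000 | deterministic seeded subsample cap per structure per plan; keeps the double kernel sum desk-scale with negligible density error (acceptance criterion 5 quantifies this) |
| `near_max_fraction` | volume fraction | 0.001 | near-max D0.1% as the maximum-dose surrogate for density-based curves, whose support is unbounded; achieved curves report the literal sample maximum |
| cut-points | Gy | heart 30; lung and lung−PTV 20, 5 | the standard esophageal-protocol metric set |
| `plan_weighting` | — | `voxel` | every retained voxel weighs equally; `plan` re-weights so each plan contributes equally regardless of organ size (both exact in the estimator) |

## What the phantom emulates — and what it does not

The synthetic cohort generator stands in for a clinical esophageal cohort:
a central elongated target ellipsoid (per-plan center jitter ±6 mm), two
large lateral lungs, a heart overlapping the target (exercising negative
$t$), and a thin posterior cord in the sparse distal tail. Voxel dose is
$x = D_{rx}\, S(t) + \eta$ with the logistic falloff
$S(t) = (1 + e^{(t - t_0)/\tau})^{-1}$, $D_{rx} = 50$ Gy, $t_0 = 10$ mm,
$\tau = 4$ mm, voxel noise $\eta$ from a Normal$(0, 1\,\mathrm{Gy}^2)$
truncated so $x \ge 0$, and a log-normal (SD 0.1) per-plan multiplier on
$\tau$ as inter-plan variability, on a $64^3$ lattice at 4 mm. These
values were chosen once as a realistic stated world — prescription-level
target dose, centimeter-scale falloff, ~1 Gy voxel noise, ~10% protocol
spread — and are not tuned to test outcomes.

Crucially, in this world dose depends on geometry *only through* $t$, so
the model's central assumption holds exactly and an analytic ground-truth
DVH exists (`true_dvh`, the mean truncated-normal survival function over
the structure's distances). A green parameter-recovery test therefore
establishes that the estimator recovers a distance-driven dose law it is
correctly specified for — it does not establish clinical accuracy on real
plans, where trade-offs between OARs, beam arrangements and planner habits
make dose depend on more than distance.

## Numerical choices

- **Distance convention.** $t$ is center-to-center: distance to the nearest
  opposite-class voxel center, so $|t| > 0$ always. A surface-interpolated
  boundary would shift every $|t|$ by about half a voxel; the
  center-to-center convention is exactly checkable against a brute-force
  nearest-neighbor oracle and is what an exact Euclidean distance transform
  yields. Anisotropic spacing is honored. If the target fills the whole
  grid, inside distances fall back to the nearest grid boundary face.
- **Rasterization.** Voxel-center even–odd (crossing parity) test, so
  ring-shaped structures with holes come out right; a test point that lies
  exactly on a polygon edge is nudged a small fraction of a voxel toward
  the polygon centroid and retested — a deterministic tie-break.
- **Boundary correction.** The dose kernel is reflected at 0 Gy; a training
  dose of exactly 0 contributes its kernel twice, which is the correct fold
  (the conditional then integrates to one over $[0,\infty)$). No correction
  at the upper end; the 10% domain headroom keeps the truncated tail mass
  below the 1e−6 normalization tolerance, and predicted densities are
  additionally trapezoid-renormalized on their axis.
- **Far queries.** If the distance-kernel weights of a query $t$ underflow
  to zero, the query is clamped into the training range (and counted in the
  log) rather than returning an undefined density: voxels far beyond the
  training geometry inherit the most distal training behavior.
- **Exact fast marginalization.** Voxel-lattice distances are heavily tied,
  so the per-patient marginalization groups duplicated $t$ values on both
  the query and training side and reduces the double kernel sum to small
  matrix products plus one weighted mixture evaluation — algebraically
  identical to the literal sum (the acceptance suite checks 1e−9
  agreement), not an approximation. Kernel contributions beyond $9h$ are
  dropped; at that cutoff the omitted terms are below double round-off.
- **Cumulative curves.** Achieved DVHs use the strict "dose higher than
  $d$" convention at every axis point, with DVH(0) defined as 1 (all
  volume receives at least 0 Gy) — the one point where the strict
  convention would disagree with the physical definition. RMSE across
  plans is $\sqrt{\sum(\text{pred}-\text{ach})^2 / N}$; the per-plan
  linear fit regresses predicted on achieved volume fractions over the
  full common axis, interpolating the coarser curve onto the finer.
- **Degenerate inputs.** Fewer than two training pairs or zero variance in
  either coordinate is a classed error naming the coordinate; an achieved
  curve with zero variance makes the linear fit degenerate — reported as
  `NA` in cohort reports, fatal only when called directly.

## Open design choices

Where the problem statement left the design genuinely open, the package
commits as follows: one model per organ class (heart, lung, lung−PTV,
cord) selected by a glob-based name-matching table, rather than a pooled
cross-organ model; the patient distance distribution $p^*(t)$ enters as
the empirical measure (exact and parameter-free) rather than being
smoothed with its own kernel; voxels pool with equal weight by default
(per-plan equal weighting available); lung−PTV is derived by Boolean mask
subtraction when not supplied. Plan I/O replaces any vendor integration
with files: a portable `plan.json` + NRRD bundle, and a deliberately
minimal explicit-VR little-endian DICOM-RT reader/writer pair whose
contract is that files it writes, it reads back losslessly (foreign DICOM
dialects are out of scope).

## Known limitations

No covariates beyond signed distance; no PTV coverage or conformity
indices (the module predicts OAR DVHs only); no plan optimizer — the
output is a QA benchmark, and flagging thresholds for re-optimization are
left to the report consumer. The near-max surrogate inherits the usual KDE
tail behavior: where training data are sparse at high dose (the distal
cord regime), predicted near-max values are smoothed upward relative to
the true maximum. The DICOM layer supports defined-length explicit-VR
little endian only.
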