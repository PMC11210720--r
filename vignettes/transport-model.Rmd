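---
title: "Regularized optimal mass transport for dynamic 3D images: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized optimal mass transport for dynamic 3D images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romt)
```

## The model

Dynamic volumetric data — prototypically dynamic contrast-enhanced MRI of a
tracer moving through the brain's glymphatic pathways — records a
non-negative intensity $\rho(t,x)$ that we treat as a mass density. The
package estimates the velocity field that carried the mass from one observed
frame to the next by solving a regularized optimal mass transport (rOMT)
problem: minimize the kinetic energy

$$\inf_v \int_0^1\!\!\int_\Omega \rho(t,x)\,\lVert v(t,x)\rVert^2\,dx\,dt
  \;+\; \beta\,\lVert\rho(1,\cdot)-\rho_1^{obs}\rVert^2$$

subject to the advection–diffusion equation

$$\partial_t \rho + \nabla\cdot(\rho v) = \sigma \Delta \rho,
  \qquad \rho(0,\cdot)=\rho_0^{obs},$$

with constant diffusion coefficient $\sigma \ge 0$. Setting $\sigma = 0$
recovers the classical Benamou–Brenier dynamic formulation of optimal
transport. The diffusion term matters for biological flows, where both bulk
(advective) motion and diffusive spreading are present and their relative
intensity — the Péclet number — is itself a quantity of interest.

Two modeling choices deserve emphasis:

* **Free end-point.** The terminal condition is imposed as a weighted
  squared mismatch (weight $\beta$) rather than as a hard constraint, so
  observation noise in the target frame is not transported literally.
* **Velocity, not momentum.** The optimization variable is $v$, not the
  momentum $\rho v$. With momentum as the variable the energy integrand
  becomes $\lVert P\rVert^2/\rho$, which blows up where $\rho \to 0$ — and
  real tracer images contain large zero-signal regions. The objective in
  $v$ stays finite there; the test suite covers a frame pair with an
  all-zero region.

## Discretization

Space is a cell-centered uniform grid of $n = n_x n_y n_z$ voxels (unit
spacing; the `ks` parameter enters the cost as a quadrature weight only).
Voxels are stored x-fastest, matching R's native array order; cell centers
sit at integer coordinates starting at 1. Time between one frame pair is
split into $m$ intervals of length `kt`.

One interval is advanced by operator splitting:

1. **Advection** by a particle-in-cell (PIC) step: the parcel at each cell
   center moves by $k_t v$ and its mass is spread onto the 8 surrounding
   centers with trilinear weights, giving a sparse matrix $S(v)$ that is
   column-stochastic — each column sums to one, so total mass is conserved
   exactly. Parcels displaced outside the domain are clamped to the
   boundary, preserving the column sums (dropping them would leak mass the
   model assumes conserved).
2. **Diffusion** by backward Euler: $\rho_{i+1} = L^{-1}\rho^{adv}$ with
   $L = I - k_t Q$ and $Q$ the 7-point stencil of $\sigma\Delta$ under
   homogeneous Neumann (zero-flux) boundary conditions. Neumann closure
   makes every row and column of $Q$ sum to zero, hence
   $\mathbf{1}^\top L = \mathbf{1}^\top$ and the implicit step conserves
   mass to solver accuracy; $L$ is a symmetric positive-definite M-matrix,
   so positivity is preserved as well. Its sparse Cholesky factor is
   computed once per (grid, $\sigma$, `kt`) and reused by every forward
   step and every sensitivity product.

The forward model is therefore the recursion
$\rho_{k} = L^{-1}S(v_{k-1})\cdots L^{-1}S(v_0)\,\rho_0$, and the discrete
objective is

$$F(v) = k_s k_t\, \boldsymbol\rho^\top M (v \odot v)
  \;+\; \beta\,\lVert\rho_m - \rho_1^{obs}\rVert^2,
  \qquad M = I_m \otimes [\,I_n\,|\,I_n\,|\,I_n\,],$$

where $\boldsymbol\rho$ stacks the interpolations $\rho_1,\dots,\rho_m$, so
each interval's squared speed is weighted by the density at the interval's
end state.

## Gauss–Newton with matrix-free sensitivities

$F$ is quadratic in $v$ given the states, and $S(v)$ is linear in $v$, so a
Gauss–Newton iteration fits naturally. The sensitivity of the states with
respect to the velocities is a lower-triangular block Jacobian (state $k$
depends only on intervals $j < k$), whose blocks combine the cached $S$
matrices, the diffusion solve, and the PIC velocity Jacobian
$B(\rho_j) = \partial (S(v_j)\rho_j)/\partial v_j$ — the analytic derivative
of the trilinear weights, scaled by $k_t$ and the source mass, one-sided at
weight kinks and zero along clamped axes so that it is consistent with the
forward map's boundary behavior.

The gradient and the Gauss–Newton Hessian action are assembled from three
matrix-free products:

* `jac_final_vec()` — forward accumulation of $J_m x$;
* `jacT_full_vec()` — a single backward (adjoint) sweep for $J^\top y$,
  algebraically identical to recursively expanding the block products but
  touching each cached matrix once (this is where the method's practical
  speed lives: all $S(v_j)$ and $B(\rho_j)$ are precomputed once per outer
  iteration, and nothing is recomputed inside the inner solver);
* the diagonal kinetic-energy term $2 k_s k_t\,\mathrm{diag}(M^\top
  \boldsymbol\rho)$.

$Hx = -g$ is solved inexactly by preconditioned conjugate gradients with the
kinetic-energy diagonal as preconditioner, followed by a backtracking line
search on the total cost. Line-search failure terminates the outer loop and
returns the current field — the conventional stopping rule for this scheme —
and a PCG breakdown falls back to the steepest-descent direction for that
iteration. Correctness of all derivative paths is pinned by
finite-difference, adjoint-identity and dense-assembly oracles in the test
suite.

### Numerical controls and defaults

The model parameters default to the published benchmark set: $m = 10$,
$k_t = 0.4$, $k_s = 1$, $\sigma = 0.002$, $\beta = 5000$. The solver
controls are not specified by the source method description and follow
common inexact-Newton practice; all are exposed in `romt_config()`:

| control | default | role |
|---|---|---|
| `gn_max_iter` | 20 | outer Gauss–Newton cap |
| `pcg_rel_tol` | 1e-2 | inner CG relative residual (inexact Newton) |
| `pcg_max_iter` | 20 | inner CG cap |
| `ls_shrink`, `ls_max_backtracks` | 0.5, 15 | backtracking line search |
| `precond` | `"diag"` | kinetic-energy diagonal or identity |

Line-search acceptance is simple decrease of the total cost (not Armijo):
the reference algorithm only asks for a step length and treats failure as
termination, and the Gauss–Newton direction with a PSD Hessian
approximation is a descent direction whenever the gradient is nonzero.
The initial guess is $v = 0$ for every loop.

Multi-frame sequences run in two modes. `chained` feeds each loop's final
interpolation into the next loop as its source — no fresh observation noise
enters, at the price of strict serialism. `independent` starts each loop
from its observed frame; loops share no mutable state and parallel
execution (`jobs`) is guaranteed to produce values identical to a serial
run.

## Lagrangian post-processing

Rewriting the advection–diffusion equation in conservation form defines the
augmented velocity $\tilde v = v - \sigma\nabla\log\rho$, under which the
dynamics are a pure transport law. Pathlines integrate
$\dot L = \tilde v(t, L)$ by explicit Euler (optionally sub-stepped) with
trilinear field sampling, seeded at voxel centers where the initial frame
exceeds 10% of its maximum (the seeding rule is a package choice; the
source describes no seed set). Two per-step attributes decorate each line:

* **speed** $s = \lVert v\rVert$ — deliberately the *optimized* velocity,
  not $\tilde v$; this asymmetry (trajectories follow $\tilde v$, speeds
  report $v$) is the method's own convention and is preserved;
* **Péclet number** $Pe = \lVert v\rVert / (\sigma\lVert\nabla\log\rho
  \rVert)$, the local advection/diffusion ratio.

The $\nabla\log\rho$ gradient uses central differences (one-sided at
boundaries) of $\log(\rho + \varepsilon)$ with
$\varepsilon = 10^{-8}\max\rho$. Where the gradient vanishes (uniform
density) the Péclet denominator is floored at `eps_log`, so attached line
values are finite but can be very large; the cap `pe_cap` (default 100) is
applied when rasterizing to a map, not on the lines themselves — capping at
attachment would saturate whole-line statistics at the benchmark's
$\sigma = 0.002$, where typical core Péclet values exceed 100. With
$\sigma = 0$ the Péclet number is infinite everywhere (pure advection) and
`attach_peclet()` refuses to fabricate a value.

Rasterization bins every sampled (point, value) pair to its nearest voxel
and averages; untouched voxels are `NA`, never a data zero. Flux vectors
join each line's first and last points, summarizing net displacement.

A caution on summarizing Péclet values: the log-density gradient vanishes
at every density maximum, so particles seeded at a blob's core start at
near-singular Pe (finite only through the `eps_log` floor). Loop-wise
*means* of pathline Pe are therefore dominated by those core samples in
early loops — which is exactly why the phantom's advection-to-diffusion
handover registers as a falling mean; a robust statistic (median) moves far
less. Maps are the better summary because the cap is applied there.

## The synthetic phantom

`sphere_spec()` / `make_phantom()` generate the 5-frame Gaussian-sphere
benchmark: $G_i = \tfrac{100}{\sqrt{2\pi}}
\exp\!\big(-\tfrac{(x-0.8i)^2+(y-0.8i)^2+(z-0.8i)^2}{2}\big)$ evaluated on a
grid of step $12/(N-1)$ ($12/49$ at the base size $N = 50$), with frame
$i \ge 1$ additionally blurred by a Gaussian filter of standard deviation
$(i+1)\cdot 0.2$ voxels. The construction interpolates continuously in $i$,
which yields approximate ground-truth intermediates for loop $i$, sub-step
$j$: center $0.8(i + j/m)$, blur $(i + j/m + 1)\cdot 0.2$. Scoring each
solver interpolation against its intermediate by mean squared error gives
the accuracy curve (`accuracy_curve()`).

Three construction details were genuinely open and are fixed as follows:

* **Grid placement.** The step is stated but not the offset. The grid is
  positioned so the origin — the first sphere's center — is a grid point
  (span $[-5.88, 6.12]$ at $50^3$ rather than exactly symmetric); this
  makes the unfiltered peak hit the analytic amplitude
  $100/\sqrt{2\pi} \approx 39.894$ exactly, which pins the construction in
  tests. Spheres advance to center 3.2, comfortably inside either span.
* **Filter units.** The blur standard deviation is interpreted in voxels —
  the convention of the standard volumetric filtering routines (e.g.
  MATLAB's `imgaussfilt3`, scipy's `gaussian_filter`). The physical-units
  alternative (converting by the grid step, i.e. up to 4.1 voxels of blur
  at $50^3$) measurably violates the construction's equal-mass premise
  (3.5–4% mass drift from domain-boundary effects), so it was rejected.
* **Scaled sizes** round half up: $N\cdot\{0.5,\dots,1.75\}$ gives 25, 38,
  50, 63, 75, 88.
* **Filter boundary.** Separable convolution with replicate (nearest)
  padding and a unit-sum kernel truncated at $4\sigma$; away from the
  boundary this conserves mass to round-off, and the phantom's mass lives
  well inside the domain.

### What a green phantom test does and does not establish

The phantom exercises the full pipeline — generation, 4 transport solves,
tracing, mapping, scoring — under exactly known dynamics: pure translation
plus isotropic blur of a smooth, compactly supported blob. It establishes
that the solver recovers mass-conserving, cost-decreasing dynamics whose
interpolations track the analytic intermediates, and that the Péclet
diagnostics reproduce the expected advection-to-diffusion handover over the
frame sequence. It does not emulate observation noise, anatomical
structure, masked irregular domains, intensity nonlinearity, or
registration error — all present in real tracer MRI — so real-data behavior
(particularly the `chained` vs `independent` trade-off under noise) is not
certified by these tests. The half-scale ($25^3$) phantom used in the
routine suite has no published reference accuracy; it is checked for
structural properties, while the $50^3$ benchmark (`scripts/phantom50.R`,
30–60 min) is the configuration with a published mean MSE.

## Degenerate inputs and numerical edges

* $\sigma = 0$ skips the solve entirely: `diffuse_implicit()` is the exact
  identity and the model is pure PIC transport.
* Trilinear weight kinks (parcels exactly on cell faces): the Jacobian uses
  the one-sided derivative of the containing cell; the finite-difference
  tests sample displacements away from the measure-zero kink set.
* Round-off negatives from the diffusion solve (an M-matrix solve is
  non-negative in exact arithmetic) are zeroed below
  $10^{-12}\max|\rho|$ — for density states only; adjoint and sensitivity
  solves are signed and unclamped.
* Grids with a singleton axis (2D problems as $n_x \times n_y \times 1$)
  are supported throughout; the degenerate axis simply carries weight 1.
* All-zero frames make the fitting optimum $v = 0$; zero regions inside
  frames are benign because the variable is $v$ (see above).

## Known limitations

* Constant isotropic $\sigma$ only; spatially varying or nonlinear
  diffusion is out of scope.
* One PIC step per interval (no sub-stepping of the advection matrix);
  displacements large relative to the blob's features lose accuracy before
  they lose mass.
* The unbalanced (source-term) transport variant and fixed-end-point exact
  matching are not implemented.
* Runtime grows steeply with grid size; the $88^3$ end of the published
  scaling study is impractical in plain R and was not attempted.
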