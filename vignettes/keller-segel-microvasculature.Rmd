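---
title: "Modeling brain microvascular network formation with a modified Keller-Segel system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain microvascular network formation with a modified Keller-Segel system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksnet)
```

## The model

Cultured brain microvascular endothelial cells (BMECs) self-organize into
polygonal, capillary-like networks. `ksnet` studies a chemotaxis model for
this process: a cell density $u(x,t)$ and a diffusible chemoattractant
$v(x,t)$ coupled as

$$
\begin{aligned}
u_t &= f(u) \;-\; b\,\nabla\!\cdot(u\nabla v) \;+\; d_u\,\Delta u,\\
v_t &= c\,u \;-\; e\,v \;+\; d_v\,\Delta v,
\end{aligned}
\qquad f(u) = a\,u\,(1-u)\,(u-\gamma),
$$

on a rectangle with zero-flux (Neumann) boundaries. Cells are produced or
removed by the bistable cubic $f$ — rest states $u=0$ (no cells) and $u=1$
(confluent cells) are stable, separated by the unstable threshold $\gamma$ —
drift up the chemoattractant gradient with sensitivity $b$, and diffuse with
$d_u$. The chemoattractant is secreted by cells at rate $c$, decays at rate
$e$ and diffuses with $d_v$.

The reference parameter set used throughout is
$a=7,\; b=10,\; c=3,\; e=2,\; d_u=1,\; d_v=10$, grid spacing $h=1$, with
$\gamma$ the main control parameter. Varying $\gamma$ through
$(0, 1)$ moves the long-time pattern through distinct regimes: homogeneous
confluence (small $\gamma$), a traveling invasion of the empty state, a
stable polygonal network around $\gamma \approx 0.25$, and a degenerate
(fragmented) network around $\gamma \approx 0.29$.

The space-free kinetics $u'=f(u),\ v'=cu-ev$ has exactly three equilibria
$(0,0)$, $(\gamma, c\gamma/e)$, $(1, c/e)$ with eigenvalues
$\{f'(u^*), -e\}$; the outer two are stable nodes and the middle one a
saddle whose stable manifold is the line $u=\gamma$:

```{r kinetics}
ode2_equilibria(ks_params(gamma = 0.25))
```

## Discretization and its guarantees

Space is discretized with cell-centered 5-point stencils; zero-flux
boundaries use mirrored ghost cells (the ghost equals the boundary cell),
which keeps the summation-by-parts structure intact. The chemotaxis term is
discretized in *conservative* (flux) form: each interior face carries flux
$\bar u_{\text{face}} (v_{nb} - v_c)/h$ with the arithmetic mean of the two
adjacent densities, and boundary faces carry none. Two exact discrete
consequences follow, both tested to round-off:

* the transport and diffusion terms telescope, so
  $\sum_{\text{cells}} \partial_t u\, h^2 = \sum_{\text{cells}} f(u)\, h^2$
  at every stage of every step — the semi-discrete analogue of the
  integral balance law, whose $v$-counterpart
  $\dot{\bar v} = c\bar u - e\bar v$ is monitored by `mean_values()`;
* the elliptic operator of the inverse problem (below) is symmetric
  positive semi-definite with kernel exactly the constants.

Time stepping is classical RK4 with $dt = 0.01$ against the explicit
stability bound $dt \le h^2/(4\max(d_u,d_v)) = 0.025$; fourth-order
convergence in $dt$ is verified by step-halving. The order of the time
integrator is a package choice — only "Runge-Kutta" behavior is prescribed
by the problem.

**Positivity.** The continuum solutions remain non-negative, and the
package monitors `min_u(t)`, `min_v(t)` every step rather than clipping.
The default arithmetic face average, being a second-order central scheme,
undershoots at the sharp fronts of the pattern-forming regimes: the
$\gamma \in \{0.2, 0.25, 0.29\}$ reference runs reach
$\min u \approx -0.04\ldots-0.05$, *independently of* $dt$ (identical at
$dt=0.0025$), i.e. a spatial artifact. The `scheme = "upwind"` option
(donor-cell face density against the drift direction $b\nabla v$) restores
$\min u \ge -10^{-6}$ on the same runs at the price of first-order accuracy
in the transport term. The default stays arithmetic; the positivity
monitor is reported honestly, and the corresponding strict acceptance
check fails for the default scheme by design rather than being papered
over.

## The synthetic world

`make_initial_condition()` reproduces the stated experiment-like start:
$u_0 = 0.2$ background with nine squares at $0.8$ (side $n_x/10$, centers
on the $(1/4, 1/2, 3/4)$ lattice of each axis) plus i.i.d.
$\mathrm{Uniform}[0, 0.2]$ noise per cell, and $v_0 \equiv 0.5$; a 100x100
grid is the default (the source imagery probes positions up to
$x \approx 54$, and this size reproduces the figure-scale morphology;
it is configurable). A fixed seed gives bit-identical fields.

What a green regime test establishes is *qualitative*: the pattern class of
the final state, not pixel-level agreement with any figure — grid size,
square size and integrator details of the original computations are
unknown. One genuine finite-size effect is documented: at $\gamma = 0.29$
the fragmented network keeps eroding, and by $t=180$ its high-density mode
holds only ~1–4% of a 100x100 domain (across seeds), below the 5%
bimodality threshold the acceptance criterion uses; on a 200x200 grid the
same run retains ~6%. The criterion is left red with this analysis; the
package's own regime label for that run is `"degenerate-network"`.

`classify_regime()` operationalizes the qualitative regime descriptions:
homogeneous means deviation $< 0.01$; bimodal means both the $u<0.3$ and
$u>0.7$ populations exceed 5% of cells; a bimodal state is a `"network"`
when the $u>0.5$ phase is essentially one 4-connected component
(largest-component fraction $\ge 0.5$) and `"degenerate-network"` when the
skeleton is fragmented; an invasion is a non-bimodal end state whose
high-phase area crossed 50% during the run, leaving a single coherent
residual region. The connectivity reading mirrors how vessel-analysis
tools characterize network integrity.

## Reconstructing the chemoattractant from image pairs

Given two consecutive density frames $u(t), u(t+\delta)$, the unknown
field $v$ satisfies the elliptic equation

$$
-\nabla\!\cdot\!\big(u(t)\,\nabla v\big) \;=\;
\frac{1}{b}\Big[\tfrac{u(t+\delta)-u(t)}{\delta} - f(u(t)) - d_u \Delta u(t)\Big],
$$

solvable up to an additive constant when $u > 0$. The package assembles
the conservative symmetric PSD operator (`assemble_operator()`), projects
the right-hand side to mean zero (the compatibility condition), and solves
with a Krylov minimal-residual iteration, fixing the gauge by a final
mean-zero projection. Because the operator is symmetric, the default
solver is MINRES (restart-free short recurrence); restarted GMRES is
available as an option but stagnates at short restarts on fine grids —
on the 64x64 manufactured problem GMRES(50) plateaus while MINRES reaches
a $10^{-10}$ relative residual in ~560 matrix-vector products.

The original microscopy frames are not deposited, so correctness rests on
manufactured problems: `make_fixture_framepair("gaussian-bumps")` builds a
smooth positive $u$, a known mean-zero $v^\ast$, and
$u_{t+\delta} = u + \delta\,[f(u) - b\nabla\!\cdot(u\nabla v^\ast) + d_u\Delta u]$,
one exact forward-Euler step — the solve must return $v^\ast$ to solver
tolerance (asserted at $10^{-6}$ relative). Raw images are prepared with
`preprocess_frame()`: min-max rescale, optional Gaussian blur, and a
positivity floor $\varepsilon = 10^{-3}$ (real frames contain $u=0$
regions that violate ellipticity). How the original 8-bit intensities were
mapped to densities is unknown; the rescale is a declared convention, and
the CLI can bypass it for frames already on the density scale.

## Three temporal phases

At fixed positions of a network-forming run, $u$, $v$ and their stencil
diagnostics traverse three regimes — very fast growth, an abrupt
chemoattractant collapse, and a slow relaxation. `segment_phases()`
operationalizes the visual reading as a continuous two-breakpoint
piecewise-linear least-squares fit over all admissible breakpoint pairs
(on sample times, exhaustive search). Two numerical choices matter:

* the fit is applied to at most 400 working samples (longer series are
  evenly subsampled): on a densely oversampled long run, plain SSE is
  dominated by the long slow tail and drifts away from the short fast
  transients;
* recovery on noiseless piecewise-linear input is exact whenever the true
  breakpoints are working-grid sample times, and the breakpoint estimate
  is invariant to affine rescaling of the signal; an exactly linear input
  is flagged `degenerate`.

On the reference $\gamma=0.25$ run at position (50, 50), the fitted phases
have slope magnitudes in strictly decreasing order (about $0.6$, $0.1$,
$0.005$ per unit time), the quantitative form of the "very fast / fast /
slow" description. Segmentation defaults to $v(t)$, whose phase
transitions are the sharpest; $u(t)$ is available as an option.

## The reduced four-dimensional model

Two identical compartments coupled by discrete diffusion and a
chemotaxis-like exchange mimic the PDE mechanism:

$$
\begin{aligned}
u_1' &= f(u_1) - b\,u_1 (v_2 - v_1) + d_u (u_2 - u_1), &
v_1' &= c u_1 - e v_1 + d_v (v_2 - v_1),
\end{aligned}
$$

and symmetrically for $(u_2, v_2)$; the system is equivariant under
swapping compartments. At stationarity the $v$-equations are linear with
unique solution $v_1 = \alpha_1 u_1 + \alpha_2 u_2$,
$\alpha_1 = c(e+d_v)/[(e+d_v)^2 - d_v^2]$,
$\alpha_2 = c\,d_v/[(e+d_v)^2 - d_v^2]$ (the printed source of these
coefficients is typographically corrupted; the package derives them from
the defining linear system and *tests the defining identity* rather than
any rendering). Eliminating $v$ reduces stationarity to the scalar
fixed-point problem $u_1 = \varphi(\varphi(u_1))$ with

$$
\varphi(u) = u + \frac{f(u)}{b\,u(\alpha_1-\alpha_2) - d_u},
$$

singular at $u = d_u/[b(\alpha_1 - \alpha_2)]$ (= $22/75$ at $b=25$).
`find_equilibria()` scans $u_1 \in [0, 2]$ on $10^4$ points (the scan
ceiling covers the asymmetric branch that exceeds $u=1$), brackets sign
changes away from the singular abscissae, refines by `uniroot` plus a full
4D Newton polish, and certifies every state to residual $< 10^{-10}$. An
independent brute-force Newton search from a $20^4$ lattice returns the
identical sets at $b \in \{10, 15, 25\}$.

```{r ode4}
scan <- bifurcation_scan(ks_params(), b_grid = c(10, 15, 25))
scan[, c("b", "n_eq", "n_stable")]
```

As the sensitivity $b$ grows, the three symmetric states (empty,
threshold, confluent) are joined first by two unstable asymmetric states,
then by four more of which two are stable — so at $b=25$ four locally
stable states coexist: empty, confluent, and an asymmetric high/low pair
with $\gamma < u_2^* < 1 < u_1^*$, the low-dimensional prototype of
high- and low-density regions coexisting in the network. Stability labels
use the analytic Jacobian with a $10^{-10}$ spectral tolerance (marginal
spectra are excluded from counts rather than miscounted near bifurcation
points); the exact $b$ values where counts jump are reported from the scan
but not asserted, as only their ordering is established. Heteroclinic
orbits launched along the unstable eigendirections of the threshold state
at $b=25$ settle at the empty, confluent, and asymmetric stable states;
along an *exact* eigendirection the opposite displacements reach either
the two symmetric fates or the two asymmetric ones, and the
asymmetric-state/origin pair of fates seen in trajectory plots requires a
mixed displacement (tested with the antisymmetric direction biased by
$-0.3$ times the symmetric one).

## Known limitations

* Figure-level reproduction of the original imagery and of the
  reconstructed fields is out of reach (frames not deposited; original
  discretization and grid unknown); all inverse-problem guarantees are on
  manufactured data.
* The default transport discretization violates strict numerical
  positivity at fronts (see above); use `scheme = "upwind"` when
  positivity matters more than second-order accuracy.
* The slow-fast structure is described empirically via changepoint fits;
  no geometric singular perturbation analysis is attempted.
* Regime labels are threshold-based operationalizations of qualitative
  descriptions; near regime boundaries in $\gamma$ they are
  seed-sensitive.
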