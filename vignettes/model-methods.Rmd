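---
title: "A mechanochemically coupled particle-spring model of eukaryotic chemotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemically coupled particle-spring model of eukaryotic chemotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chemomech)
```

# The model

`chemomech` simulates a single crawling cell — a neutrophil- or
*Dictyostelium*-like amoeboid walker — as a two-dimensional particle-spring
body coupled to a membrane-bound signalling network and a strain-gated
mechanosensing pathway.  The three ingredients and the way they close on one
another are:

1. **Mechanics.**  The membrane is a closed ring of nodes connected by
   Kelvin–Voigt elements (spring of stiffness $k$ in parallel with a dashpot
   of viscosity $\eta$); each node is also anchored to the substrate through
   an effective friction $\mu$.  The motion of membrane node $i$ is the
   overdamped force balance
   $$\mu \mathbf v_i = \mathbf F^{elas}_i + \mathbf F^{vis}_i +
     \mathbf F^{pro}_i + \mathbf F^{cont}_i + \mathbf F^{drag}_i
     + \mathbf F^{area}_i ,$$
   with protrusion and contraction slaved to the signalling state (below).
   The lamellipodial interior is a cloud of nodes joined by the edges of the
   Delaunay triangulation, each edge a zero-rest-length spring; because the
   interior relaxes much faster than the membrane moves, interior node
   positions are taken quasi-statically from
   $\sum_{j \in N(i)} (\mathbf X_j - \mathbf X_i) = 0$, i.e. every interior
   node sits at the mean of its Delaunay neighbours, with the membrane ring
   as Dirichlet boundary.

2. **Signalling.**  All reaction–diffusion takes place on the membrane ring,
   treated as a periodic 1D lattice with node-centred arc lengths as the
   finite-difference metric; cytosolic pools are well mixed.  Three layers:
   *(i)* a receptor layer implementing balanced inactivation — the
   attractant signal produces a membrane-bound activator ($G_{\beta\gamma}$
   proxy, identified with PAK1 activity $E_p$) and, at the same total rate, a
   fast cytosolic inhibitor ($G_\alpha$ proxy, identified with Lsc1 activity
   $E_\rho$ once membrane-bound); their mutual annihilation turns a few
   percent of front-to-back attractant difference into a strongly polarised
   activator field.  *(ii)* Rac/RhoA: active membrane fractions $R, \rho$
   obey
   $$\partial_t G = D_m \nabla^2 G + P_G (1+\xi)\, G_i - \delta_G G + Q_G G,
     \qquad P_R = I_R + \alpha E_p,\quad P_\rho = I_\rho + \tau E_\rho,$$
   with $G_i$ the inactive cytosolic concentration from the conservation
   law, $\xi$ a zero-mean multiplicative noise (the endogenous stochastic
   signal that lets an unstimulated cell polarise), and $Q$ the
   FilGAP-mediated antagonism
   $$Q_R = -\frac{1}{1 + A_G e^{-b\,[\mathrm{FilGAP}]\,[\mathrm{PIP_3}]}},
     \qquad Q_\rho = -Q_R,$$
   an ultrasensitive switch that turns released cytosolic FilGAP into a
   local Rac sink and RhoA source wherever PIP$_3$ is high.  Because the
   positive branch of $Q$ converts *inactive* protein, it is gated by
   cytosolic availability (clamped $G_i$ fraction); otherwise the source
   term would mint active RhoA from an empty pool once $Q_\rho$ exceeds
   $\delta_G$.  *(iii)*
   Phosphoinositides: PIP$_2$ and PIP$_3$ interconvert through membrane-bound
   PI3K and PTEN, whose finite molecule numbers translocate stochastically
   from the cytosol (Monte-Carlo binding biased by PIP$_3$ and active Rac for
   PI3K; PIP$_2$ and active RhoA for PTEN), and whose *catalytic activity*
   is gated by the local GTPase (a steep Hill factor in active Rac for PI3K
   and in active RhoA for PTEN — the enzymes are effectors activated by the
   GTPase layer).  PI3K recruitment by its own product is the autocatalytic
   loop that grows a single PIP$_3$ patch out of molecular noise; the
   Rac gate on its catalysis is what lets the FilGAP brake extinguish a
   patch.  The patch defines the cell front.

3. **Mechanosensing.**  Every (triangle, corner) of the lamellipodial
   network is an FLNa crosslink holding $m_i$ FilGAP molecules (capacity
   $m_{i0}$).  A corner whose angular strain $\Delta\theta_i$ (current minus
   reference corner angle) stays inside the band $[\beta_1, \beta_2]$
   releases slowly; outside the band it releases fast:
   $$\frac{dm_i}{dt} = A\,w\,\frac{m_{i0}-m_i}{\sum m_{i0} - \sum m_i}
     - \bigl[k_{slow} + (k_{fast}-k_{slow})\,\mathrm{sng}(\Delta\theta_i)\bigr]\,m_i .$$
   Released FilGAP joins the uniform cytosolic pool that drives $Q$; the
   total budget (bound + cytosolic) is conserved exactly.  Because motion
   deforms the network, this pathway is a delayed, activity-dependent brake:
   protrusion → strain → FilGAP release → Rac suppression at the
   PIP$_3$-rich front → patch turnover.

The closed loop — noise nucleates a PIP$_3$ patch, the patch protrudes, the
protrusion strains the network, the strain releases the brake, the brake
extinguishes the patch, and an adjacent region (slightly pre-amplified by
diffusion) nucleates the next one — produces the correlated random walk of
an unstimulated cell.  A shallow attractant gradient does not replace this
cycle; it only biases where the next patch forms.

# Numerical scheme

One master step (default $\Delta t = 0.5$ s) performs, in order:
environment sampling at the membrane nodes; signalling (receptor layer →
Rac/RhoA → phosphoinositides, each sub-stepped to its own stability limit);
angular strain and FilGAP release; force assembly and the membrane update;
obstacle projection; interior relaxation; retriangulation with crosslink
carry-over; geometry refresh.

Choices that matter:

* **Amount-based bookkeeping.**  Membrane species are stored as per-node
  amounts (concentration × node-centred arc length).  Membrane stretching
  dilutes and compression concentrates species with no artificial mass
  change; all diffusion is conservative flux-form finite differencing on
  the non-uniform periodic lattice.
* **Heun (explicit trapezoidal) reaction sub-steps.**  Second-order accuracy
  lets short fixture trajectories match dense ODE integrations to $10^{-6}$;
  positivity is protected by mass-preserving clipping (for the PIP pair, a
  pairwise back-transfer that cannot change the total).
* **Linearly implicit membrane step.**  The parallel spring–dashpot edge
  elements make an explicit update unconditionally unstable for the
  shortest ring modes once $\eta/\mu$ exceeds roughly $1/4$ (the dashpot
  force is proportional to the previous step's rate, giving a two-step map
  with root product $> 1$).  Velocities therefore solve
  $(\mu I + C + \Delta t\,K)\,\mathbf v = \mathbf F$ with $C$ the dashpot
  matrix and $K$ the current spring stiffness — one $2N\times 2N$ dense
  solve per step at $N = 45$.  Active forces stay explicit; each node's
  displacement is capped at $0.2$ membrane spacings (capped nodes are
  logged).
* **Interior relaxation** is a Jacobi-preconditioned conjugate-gradient
  solve of the interior graph Laplacian, warm-started from the current
  positions, converged to an $\infty$-norm residual below $5\times 10^{-9}$
  μm.
* **Retriangulation cadence.**  The Delaunay triangulation (via
  `interp::tri.mesh`) is recomputed every `remesh_every` master steps
  (default 2; per-step displacements are capped far below the membrane
  spacing, so consecutive-step topology changes are rare) and clipped to the
  (possibly concave) membrane polygon by a centroid-in-polygon test.
  Corners whose vertex triple persists keep their reference angles and
  FilGAP load; vanished corners surrender their load to the cytosol
  (budget-exact); new corners are born strain-free with the mean capacity.
  Reference angles of persisting corners are never reset, so strain
  accumulates over a corner's lifetime.
* **Excluded volume.**  Non-adjacent membrane nodes closer than $0.8$
  spacings repel linearly.  Without this guard a strongly contracting rear
  can pinch the polygon into self-intersection, which is treated as a fatal
  integrity error.
* **Determinism.**  Three RNG streams (endogenous noise, Monte-Carlo
  translocation, mesh jitter) derive from the master seed through a
  counter-based splitter, so changing one protocol knob never perturbs an
  unrelated stream; identical configuration + seed reproduces a run
  bit-for-bit.

# Design choices on under-determined points

Several ingredients are fixed here as the package's own modelling choices:

* **Cooperative enzyme binding** (`bind_coop = 2` means the binding share is
  quadratic in the local lipid concentration; the shipped default is
  stronger).  Proportional (linear) binding allocates enzymes across many
  simultaneous stable patches; cooperative recruitment is the minimal
  winner-take-all closure that yields the single dominant patch and
  all-or-none polarity the biology shows.  Setting `bind_coop = 1` recovers
  proportional binding.
* **First-order FilGAP release.**  The release term acts as a rate constant
  multiplying the current load $m_i$ (not a bare subtraction, which would
  drive $m_i$ negative); "release constant" semantics and the $0 \le m_i
  \le m_{i0}$ invariant both demand it.
* **Return gated by cytosolic availability** ($w = $ FilGAP$_c$/FilGAP
  total): without it the cytosolic pool could go negative while the network
  refills.
* **Strain band $\pm 0.35$ rad.**  Under the fixed-reference convention a
  migrating cell's corner strains have median magnitude $\approx 0.2$ rad,
  so the band must sit above that scale for the bandpass to discriminate
  actively deforming regions from the ambient plastic flow of the mesh.
* **The FilGAP concentration entering $Q$ is the cytosolic pool**, so
  locality enters only through PIP$_3$; the released brake acts wherever the
  front is.
* **Active force thresholds are polarity-relative**: protrusion (contraction)
  applies only where PIP$_3$ (PIP$_2$) exceeds its length-weighted spatial
  mean, with a saturating Hill response ($h = 2$) bounding each force.
* **Chemotaxis index** is the windowed mean cosine between the direction of
  centroid motion (resampled at 10 s) and the centroid-to-source direction:
  $-1$ dead away, $+1$ dead on.  The alternative net-displacement /
  path-length definition is available from the same trajectory data; the
  cosine form is the default because it satisfies every printed constraint
  on the published curves.
* **Attractant field** $C(r) = C_0 r_0 / \max(r, r_0)$ (steady point-source
  far field).  At the shallow gradients studied here only the percentage
  difference across the cell matters, which the placement routine controls
  exactly; an exponential profile is also provided, whose gradient
  percentage is distance-independent and set by the decay length instead.

# What the defaults represent

The default configuration is a 10 μm cell with 45 membrane and 421 interior
nodes run at $\Delta t = 0.5$ s — the study conditions of the experiments the
package reproduces.  Parameters printed nowhere (diffusivities, rates,
force scales, the strain band) ship as a calibrated profile: they were fixed
once so that the default cell migrates spontaneously at ≈ 4 μm/min with a
single PIP$_3$ patch forming within the first 100 s, shows the
velocity-then-FilGAP lag, and reproduces the mutant ordering (fast
FilGAP-null, slow FilGAP-overexpressing, immobile PI3K-null, fast
PI3K-overexpressing); every default is overridable and should be treated as
calibrated-not-published.  Totals are stated as line densities along the
membrane (μM·μm) and enzymes as molecule counts (1000 molecules per nominal
μM); the FilGAP budget is in μM equivalents.

Problem sizes used by the shipped analyses: spontaneous-migration runs are
900 s; gradient mutant runs apply the source at 500 s and continue to
1300 s with the late stage taken as the final 500 s (the reversal protocol
runs to 2100 s); sweeps use 10 independent seeds per condition.

# What the synthetic runs do and do not show

The simulations emulate: correlated random migration with pseudopod
alternation; gradient sensing down to ~2% with perpendicular and opposite
source placements; FilGAP/PI3K dose responses; obstacle contact with
flattening, extra FilGAP release, and escape along a gradient.  They do not
model: cell–substrate adhesion dynamics, explicit actin/myosin fields,
nucleus or organelles, fluid–structure interaction, attractant consumption
or obstacle-induced distortion of the chemical field, or cell–cell
interactions.  Passing tests therefore say nothing about adhesion-dependent
phenomena or about absolute molecular copy numbers; concentrations are in
nominal units anchored only by the calibrated behaviour.

# Degenerate inputs and failure modes

Non-simple (self-intersecting) membrane polygons, clockwise orientation,
zero-length edges, negative concentrations or stimuli, and disconnected
interior nodes are fatal integrity errors; runs abort with the offending
time and seed attached to the condition.  Co-circular Delaunay ties are
broken by a seed-derived $10^{-9}$ μm jitter at mesh construction.  A node
exactly at an obstacle centre projects along a fixed convention ($+x$).
Interior nodes that escape a strongly concave membrane (possible because
the harmonic relaxation only guarantees containment in the convex hull of
the neighbours) are pulled back towards the membrane centroid.

# Known limitations

* At the calibrated defaults, alignment with a shallow perpendicular
  gradient is intermittent: the strain-released brake keeps repolarising
  the cell, so the late-stage chemotaxis index fluctuates around small
  positive values rather than settling near +1, while a reversal protocol
  (source behind the cell) reliably attains a near-perfect transient
  alignment.  Stronger receptor gain steadies alignment but lets the
  gradient drive override the FilGAP brake, erasing the mutant phenotypes.

* The interior network is quasi-static; lamellipodial inertia-free flow is
  represented only through the membrane–lamellipod drag coupling.
* Obstacles are hard and frictionless; cells glide along them without
  adhesion.
* The balanced-inactivation receptor layer is a two-species abstraction;
  receptor kinetics, G-protein cycling and Cdc42 are not resolved.
* Enzyme translocation uses a simple per-step Monte-Carlo scheme, not an
  exact stochastic simulation; at the default step size binding
  probabilities stay far below 1 and the mean-field limit is recovered in
  expectation (verified in the test suite).
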