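---
title: "The compressed-graph layout model: forces, integrators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The compressed-graph layout model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaspring)
```

# The problem

RNA secondary structures are conventionally drawn with two norms in mind:
base pairs within a stem are equidistant, and loops — hairpins, bulges,
internal loops, multiloops, and the exterior region — are circular.
Force-directed ("spring embedder") layouts with one vertex per nucleotide
achieve untangled drawings but violate both norms and cost $O(N^2)$ per
iteration in the all-pairs repulsion. `rnaspring` instead lays out a
*compressed graph*: one vertex per loop and one per stem base pair, joined
by edges along the stems. For a pseudoknot-free structure this graph is a
tree with far fewer vertexes than nucleotides, and the drawing conventions
are enforced *constructively* when the converged vertex positions are
expanded back to nucleotide coordinates.

# The force model

Let $P^i$ be the position of vertex $i$. The unit vector from $j$ to $i$ is
$U(P^i,P^j) = (P^i-P^j)/|P^i-P^j|$. Two forces act:

* **Repulsion**, only between loop vertexes:
  $R(P^i,P^j) = \dfrac{G}{|P^i-P^j|^2}\,U(P^i,P^j)$.
  Restricting repulsion to loops keeps loops apart (they are the extended
  objects that must not overlap) and reduces the quadratic cost to the loop
  count.
* **Attraction**, along every graph edge:
  $A(P^i,P^j) = K\left[(P^j-P^i) + r_{\mathrm{ideal}}\,U(P^i,P^j)\right]$,
  a spring with rest length $r_{\mathrm{ideal}}$ that vanishes exactly at
  the ideal separation.

The simulation stops when every free vertex's net force magnitude is at
most $\varepsilon$. An equivalent family of stopping rules thresholds the
per-step *movement* instead; for the explicit update the two differ only
by the factor $\Delta t$. The package uses the force form, and no
conclusion below depends on the choice.

## Rest lengths and loop radii

There is no canonical numeric rest length, so the package fixes the scale
once:
one layout unit per nucleotide spacing ($s = 1$). Consecutive stem pairs
rest at $r_{\mathrm{ideal}} = s$. A loop whose perimeter carries $m$ slots —
one per unpaired base plus two per incident stem — is drawn with radius

$$\rho(m) = \frac{s}{2\sin(\pi/\max(m,3))},$$

the circumradius of a regular $m$-gon of side $s$, so that adjacent slots
sit one spacing apart; $\rho$ is also the rest length of the loop's edges
to its stems. These choices realise "round loops and equidistant base
pairs" with a uniform arc spacing and are the package's own calibration.

## Ideal positions

With centre-targeted attraction alone, stems reach the right *distance*
from their loops but not the right *direction*: converged layouts show
stems folded across loops. The remedy is to give each loop an *anchor*
per incident stem: a point on its circle, at the angular slot the stem
occupies in the loop's perimeter walk. The terminal base pair of each stem
is attracted to its anchor with rest length zero (the anchor *is* the ideal
position), which orients the stem relative to its parent loop. On every
other edge the plain attraction is kept.

Two design points here were genuinely open, and both were settled by
experiments you can reproduce with the package:

* **Anchor frame.** Anchors must rotate with the loop. Slaving the frame to
  a single reference stem (the first in the perimeter walk) locks
  multibranch loops whose actual stem angles disagree with the designed
  slots into frustrated states: we observed a 75-nt fixture pinned at a
  maximum net force of 4.4 for more than 20&#8239;000 implicit steps. The
  frame is instead fitted to *all* incident stems by a circular mean — the
  least-squares rotation of the designed anchor directions onto the current
  stem directions — which exerts no net torque about the loop. For a
  single-stem loop (hairpins, and any loop with one stem) this reduces
  exactly to the reference-stem rule.
* **Action–reaction.** If the base pair is pulled toward the anchor while
  the loop keeps its centre-targeted spring, the anchor spring is
  non-reciprocal and the molecule acquires a net thrust: layouts drift
  indefinitely instead of equilibrating (we observed hairpins wandering
  across the canvas at constant residual force, and 7 of 20 test structures
  failing to equilibrate). The loop therefore receives the
  equal-and-opposite reaction of each anchor spring, implemented as a
  rest-zero attraction toward $P^{\mathrm{bp}} - (\text{anchor offset})$.
  With reciprocity restored, all 20 structures of the graded test suite
  equilibrate in 59–307 implicit steps.

Anchors are recomputed from the frozen step-$n$ positions at every step
(not cached), so they follow the layout as it deforms.

# Integrators

Both integrators treat the model as first order: force directly sets the
displacement rate.

**Forward (explicit) Euler** updates all vertexes simultaneously from
forces at step $n$. On a linearised spring of stiffness $K$ the
displacement error is multiplied by $1-\Delta tK$ per step, so the scheme
is stable only while $|1-\Delta tK| < 1$.

**Backward (implicit) Euler** requires $P^i_{n+1} = P^i_n + \Delta t\,
f(P^i_{n+1})$ with neighbours frozen at step $n$, i.e. each vertex solves an
independent two-dimensional root problem for the residual
$F(q) = -q + P^i_n + \Delta t f(q)$; all solutions are committed
simultaneously (a Jacobi sweep, chosen for determinism and
order-independence). The root is found by Newton's method with the
analytic $2\times2$ Jacobian assembled from the closed-form partials of
the repulsion, attraction, and unit-vector terms; the $2\times2$ system is
solved in closed form. On the linear spring the implicit amplification is
$1/(1+\Delta tK) < 1$ for every positive $\Delta t$: unconditionally
stable, which is what buys the 300-fold larger time-step.

Numerical choices:

* **Newton budget**: at most `newton_iterations` (5 in the shipped implicit
  configuration) iterations per vertex-step, with early exit once the
  residual norm falls below $10^{-9}$.
* **Seeding**: the natural seed is the explicit update. At large
  $\Delta t K$, however, the explicit guess can overshoot *past* a
  neighbour onto the wrong branch of the residual (for the scalar spring at
  $x_n=2$, $K=10$, $\Delta t=3$ the explicit guess is $-28$, and Newton
  from there converges to the spurious root $-28/31$ instead of the
  physical $32/31$). The step therefore seeds with whichever of the
  explicit guess and the unmoved current position has the smaller residual
  norm; for small displacements the explicit guess always wins, so the
  normal behaviour is unchanged.
* **Singular Jacobians** ($|\det D| < 10^{-12}$): the vertex keeps its
  explicit seed for that step.
* **Coincident vertexes**: the unit vector is undefined at zero distance;
  the engine applies a deterministic jitter of $10^{-6}$ units in a fixed
  direction derived from the vertex id and retries.
* **Divergence**: any coordinate beyond $10^9$ or non-finite flags the run
  as diverged (a result, not an exception) — this is how the explicit
  integrator fails at large time-steps.

A property worth knowing: with neighbours frozen, a *pair* of connected
vertexes relaxes with amplification $-(\Delta tK-1)/(\Delta tK+1)$ per
Jacobi sweep — about $-29/31$ at the shipped implicit parameters. The
implicit scheme is therefore unconditionally stable but its slowest modes
oscillate with slowly shrinking amplitude, which bounds how tight a
stopping threshold is worth setting (see "Known limitations").

# Initialisation and placement

Nucleotides are first laid on a circle of radius $Ns/2\pi$ at equal arc
spacing; each vertex starts at the centroid of its member nucleotides
(an empty exterior region starts at the centroid of its stem anchors).
After convergence, placement is constructive: the two bases of each pair
sit symmetrically about their vertex, perpendicular to the local stem axis
(the direction between the vertex's stem-side neighbours) and one
`pair_width` apart — the pair width has no canonical value and defaults
to the same spacing $s$; unpaired loop bases sit exactly on their loop's
circle at their perimeter slots. Loop circularity is therefore exact by
construction; stem equidistance is inherited from the converged vertex
positions. SVG output draws the backbone polyline, one tick per pair and
one glyph per base, with the native SVG y-down convention.

# The synthetic-structure generator

Tests and experiments need valid inputs without downloads. The generator
builds a structure of exactly $n$ nucleotides by recursive interval
subdivision — choose a stem length, then with probability `branch_prob`
split the interior into a two-branch multiloop, otherwise continue through
internal/bulge loops or terminate in a hairpin — so non-crossing holds by
construction, stems have at least `min_stem` (default 2) stacked pairs and
hairpins at least `min_hairpin` (default 3, the physical minimum) unpaired
bases. Sequences are filled in with canonical and wobble pairs on paired
positions. The generator emulates the *size gradient* of real test sets
(tens to hundreds of nucleotides) but none of their thermodynamics: stem
lengths and branching are statistically plausible, not energy-derived, so
a green test certifies the geometry and numerics of the layout engine, not
biological realism. A shipped 76-nt cloverleaf (synthetic, tRNA-like:
acceptor stem plus three hairpin arms on one multiloop) serves as the
canonical small case.

# Shipped configurations

| parameter | explicit (1) | implicit (2) |
|---|---|---|
| integrator | Forward Euler | Backward Euler |
| $K$ | 10.0 | 10.0 |
| $G$ | 0.01 | 0.01 |
| $\Delta t$ | 0.01 | 3.0 |
| $\varepsilon$ | 0.0001 | 0.3 |
| Newton iterations | — | 5 |
| iteration cap | 200&#8239;000 | 2&#8239;000 |

The caps replace a wall-clock timeout with a hardware-independent bound,
sized so both configurations finish at desk scale on structures up to
about 400 nt. The explicit configuration's time-step is the largest its
stability region allows (on the pinned two-loop spring, $\Delta t K < 2$);
the implicit configuration's is 300 times larger.

```{r dichotomy}
sys <- two_loop_system(separation = 2)
base <- sim_config("forward", K = 10, G = 0.01, dt = 1, epsilon = 1e-4,
                   max_iterations = 5000, use_ideal_positions = FALSE)
stability_scan(sys$graph, base, "forward",
               c(0.01, 0.1, 0.19, 0.21, 3.0), init_state = sys$state)$table
```

# Known limitations

* **Pseudoknots** are out of scope: parsers reject crossing pairs and
  extended bracket families.
* **Stopping threshold vs. drawing precision.** Stopping at net force
  $\varepsilon$ with spring constant $K$ admits stem-edge length errors of
  order $\varepsilon/K$. At the shipped implicit configuration
  ($\varepsilon = 0.3$, $K = 10$) the measured relative spread of
  intra-stem spacings at the stopping point is about $0.1$–$0.2\%$;
  driving it below $0.1\%$ requires $\varepsilon \approx 0.03$ (the
  oscillatory Jacobi pair mode above is what keeps stem stretch loaded at
  the stopping threshold). Users wanting print-exact equidistance should
  simply tighten `epsilon`; convergence to $10^{-3}$ costs a few hundred
  extra implicit steps on small structures.
* **Untangling is not guaranteed**: the overlap score of a converged
  layout is usually small and the ideal-position forces reduce it
  substantially, but some topologies retain crossings that an interactive
  user would resolve by dragging (not implemented here).
* The per-vertex decoupled implicit solve trades some convergence speed
  for determinism and order-independence; a coupled or sequential solver
  would damp pair modes faster but is deliberately out of scope.
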