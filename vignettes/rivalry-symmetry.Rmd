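---
title: "Symmetry analysis of rivalry networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry analysis of rivalry networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalnet)
```

This vignette documents the mathematical method, the modeling and numerical
choices, and the limitations of the pipeline. The running example is the
conventional four-dot display: each eye sees four dots of one pure color,
and subjects report alternations among percepts, including color patterns
never shown to either eye.

## 1. Networks

A network is specified by *attribute columns* (one per stimulus attribute,
with one node per level), *learned patterns* (one level per column, one
pattern per presented image), and a *feature specification*. Construction
rules:

- nodes within a column are all-to-all coupled by inhibitory arrows, typed
  by the column's attribute type;
- nodes within a learned pattern are all-to-all coupled by excitatory
  arrows; a pair lying in p patterns receives one arrow of multiplicity p;
- an excitatory arrow's *class* is its feature tuple: the attribute types
  of its endpoints, whether the two nodes carry the same level (the level
  feature), and the geometric distance between the columns (the distance
  feature, when column coordinates are given). Pairs with unequal attribute
  types produce two directed arrows in distinct classes.

The Hebbian rationale: couplings learned under the same conditions —
between equidistant dots, between same-color levels — have equal strength;
nothing else is assumed equal. Distances are rounded to nine significant
digits before comparison so that ideal coordinates entered in floating
point land in the same class.

```{r network}
nw <- paper_network("four-dot-conventional")
glance(nw)
```

## 2. Symmetry group

The symmetry group is the automorphism group of the node set preserving the
node coloring (attribute type) and every arrow class with multiplicity.
Internally a relation matrix with the diagonal holding the node class and
entries holding concatenated arrow-class labels is built, and automorphisms
are found by most-constrained-first backtracking over signature-compatible
candidates. A naive method enumerating all n! permutations is kept as an
oracle (`automorphism_group(nw, method = "naive")`) and tested for
equivalence on all networks with at most eight nodes.

```{r group}
g <- automorphism_group(nw)
group_name(g, nw)
```

`level_swap_elements()` finds the group elements that fix every column
setwise; the *canonical eye swap* ρ is the unique such element nontrivial
in every column the group can move. For displays where the published
analysis names several commuting swaps (e.g. ρ and τ in the Hong–Shevell
display), the canonical element is their product. Fixed-point subspaces of
subgroups are synchrony subspaces; the fixed-point subspace of the whole
group is the maximal fusion state.

## 3. Isotypic decomposition

The n-dimensional node-permutation representation is decomposed over the
reals by averaging conjugates of a random symmetric matrix (seed fixed, and
the result verified independent of the draw): eigenspaces of the resulting
generic equivariant operator are irreducible copies, which are merged into
isotypic components when their characters agree. Verifications performed on
every run: the Frobenius–Schur indicator of every copy is 1 (all groups
arising here have only real-type irreducibles; anything else aborts),
component dimensions sum to n, bases are orthonormal, and every span is
invariant. Canonical bases (orbit projections for one-dimensional types,
echelon bases otherwise) make printed components reproducible.

```{r isotypic}
an <- analyze(nw)
tidy(an$decomposition)
```

A component is *fusion-breaking* when ρ acts on it as minus the identity:
a Hopf bifurcation with its center subspace there produces oscillations in
which the two eyes' levels alternate in antiphase, i.e. rivalry rather than
fusion. Components where some level swap acts trivially are additionally
annotated `leads_to_fusion`: oscillations there leave part of the display
fused. `decomposition_report()` merges the ρ-trivial components into a
single fusion block, reproducing the compact published presentation
(dimensions 1, 1, 2, 4 for the four-dot networks).

## 4. Branch catalog

For a fusion-breaking component, the equivariant Hopf theorem guarantees
periodic solution branches with specific spatiotemporal symmetries. The
catalog implemented covers the representation types that occur in these
networks:

- one-dimensional types: a single *pure antiphase* branch; nodes with zero
  basis entry become fused constants at twice the frequency;
- the two-dimensional standard representation of D3: rotating wave
  (third-period shifts), two-in-phase, and fused-node standing solutions;
- the two-dimensional standard representation of D4: antiphase standing,
  fused-node standing (double-frequency pairs), and rotating wave
  (quarter-period shifts).

Anything else raises an explicit "outside the branch catalog" error rather
than guessing.

*Combined branch.* When a network has several flagged one-dimensional
components that each lead only to partial fusion (the Hong–Shevell
two-color display), no single component predicts full rivalry — the sign
class where both swaps act as −1 has zero multiplicity. The generic
oscillation combines the components: one independent wave per component,
remaining nodes fused. This design choice reproduces the published four
alternation regimes, enumerated by `enumerate_alternation_cases()` as one
binary choice (constant level above or below the oscillation) per fused
orbit.

Branches are rendered with the phase-shifted cosine templates
x_θ(t) = cos(2π(t + θ)), independent waves offset by δ = 0.2 so that
their switching times interleave; percepts are the per-column unique
activity maxima, compressed to one cycle. Percept sampling uses grid
midpoints so that exact waveform crossings are not registered as spurious
one-sample fused percepts.

## 5. Rate equations

Each node carries activity E and fatigue H:

eps dE/dt = −E + G(I + Σ_c w_c E_src − β Σ_rivals E − g H),  dH/dt = E − H

with the Naka–Rushton gain G(z) = z²/(σ² + z²) for z > 0. One weight per
excitatory class; equal weights recover the classical model. The right-hand
side is exactly equivariant for symmetric inputs (checked to 1e−10 at
random states), fusion equilibria are found by damped Newton on the orbit
quotient (residual < 1e−10), and the analytic Jacobian is
block-diagonalized by the isotypic bases tensored with the internal (E, H)
dimensions; the block spectra reproduce the dense spectrum to 1e−7.

**Default parameters and a deliberate deviation.** Defaults are ε = 0.1,
g = 2, β = 2, w = 0.75, I = 1, σ = 1. The literature's illustrative value
β = 1 was *not* adopted: for the two-node model the fusion-breaking Hopf
condition is a·β = 1 + ε with a = G′(u*) ≤ 0.65 at any equilibrium, so no
crossing exists at β = 1 and the model could never oscillate. At β = 2 the
two-node fusion state is unstable at the default g = 2 (rivalry out of the
box) and restabilizes through a Hopf point at g ≈ 4.204, which
`hopf_scan()` locates by per-component eigenvalue tracking plus bisection
(parameter tolerance 1e−6) and which matches the closed-form condition to
1e−8.

Simulation uses `deSolve::lsoda` with absolute and relative tolerances
1e−10. `classify_spatiotemporal()` estimates the period by autocorrelation
of the first principal coordinate (parabolic peak refinement), phase-averages
one cycle, and reports for every group element the phase shift minimizing
the permuted-versus-shifted discrepancy; elements with small residual form
the spatiotemporal symmetry group of the orbit, which is compared against
`branch_symmetry()` of the predicted branches.

```{r simulate}
sim <- simulate_rivalry(analyze("conventional-monkey-text"), duration = 150)
tidy(sim$spatiotemporal)
```

## 6. Problem sizes and limitations

- Intended scale: laboratory displays, n ≤ ~20 nodes and group orders up to
  a few hundred; the naive automorphism oracle is limited to n ≤ 16 by
  design. The backtracking search handles the 12-node, order-144 six-area
  network in well under a second.
- The decomposition aborts on non-real irreducible types (complex or
  quaternionic), which do not occur for the dihedral-type groups of these
  displays.
- The branch catalog covers 1-D types and standard D3/D4 2-D types only;
  higher-dimensional or exceptional types raise an error.
- Stability of the predicted branches is not decided by the catalog —
  simulation realizes whichever branch is dynamically stable at the chosen
  parameters; for strongly synchronizing excitation that is typically the
  pure antiphase branch.
- The percept model uses deterministic templates; stochastic dominance-
  duration statistics (Levelt's propositions, gamma-distributed dwell
  times) are out of scope.
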