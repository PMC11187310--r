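---
title: "Detecting composite knots in protein backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting composite knots in protein backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotscan)
```

## The problem

A protein backbone can be knotted, and in rare cases it can carry two
sequential knots — a *composite* knot, written 3~1~#3~1~ when both
components are trefoils. Finding such proteins needs three ingredients:
a way to decide the knot type of an open curve, a way to localize the
knotted cores along the chain, and a way to enumerate candidate
proteins whose domain architecture could carry two knots at all. This
package implements all three, plus the buried-interface quantification
used to reason about dimer formation and a gene-arrangement taxonomy for
fusion evolution.

## Knot typing of an open chain

A knot is only defined for a closed curve, so an open backbone is closed
stochastically: both termini are extended to independent random points
on a sphere centered at the chain centroid (radius = 2 x the chain's
maximal centroid distance by default) and joined far outside it. Each
closure is then typed, and the chain's knot type is the majority call
with its `support` — the fraction of closures agreeing. A deep knot is
insensitive to how it is closed and reaches support near 1; a surface
entanglement wobbles around 0.5. The default is 100 closures with a
mandatory seed (`closureConfig()`), and the call is demoted to
"unresolved" when support falls below 0.5 (a strict majority).

Before typing, the chain is simplified with KMT reduction: a vertex is
deleted whenever the triangle spanned with its two neighbours is pierced
by no other segment of the chain, until nothing can be removed. For
closed curves this provably preserves the knot type; for open chains the
endpoints are pinned. Reduction shrinks a few-hundred-residue backbone
to a handful of vertices and makes the diagram computation cheap. The
piercing test is conservative: geometrically ambiguous configurations
(coplanar contacts, grazing hits within tolerance) block removal rather
than risk a topology change.

## The invariant: Alexander determinants at t = -1 and t = -2

Each closed curve is projected along a deterministic sequence of
directions (a Fibonacci-sphere sweep; a projection is rejected and
retried if any crossing is degenerate). From the diagram's crossings the
Alexander matrix is built, one row per underpass; deleting one row and
column and taking the determinant gives the Alexander polynomial up to a
unit `±t^k`. The package computes the polynomial *exactly*: the
determinant is evaluated modulo two 31-bit primes at enough integer
points to interpolate all coefficients, the coefficients are lifted
symmetrically and cross-checked between the primes, and `|Δ(1)| = 1` is
verified as a diagram-validity guard (any failure triggers a new
projection). The reported invariant pair is

- `det1 = |Δ(-1)|` — the knot determinant, and
- `det2 = |Δ(-2)|`.

Both are multiplicative under connected sum and blind to chirality. The
pair is looked up in a fixed table covering knots through six crossings
plus the double trefoil. The pair matters: the determinant alone cannot
tell the granny/square knot 3~1~#3~1~ (det1 = 9, det2 = 49) from 6~1~
(det1 = 9, det2 = 20). Because the Alexander determinant cannot see
chirality, the composite label is reported as 3~1~#3~1~ without
distinguishing granny from square knots.

## Localizing knotted cores

`knotFingerprint()` types every subchain on a grid of start/end
positions (stride 5 residues, 20 closures per entry by default — the
coarse pass only has to flag regions, not measure them).
`locateCores()` then takes the shortest knotted grid entry, expands it
by one stride, and trims both ends alternately one residue at a time,
re-typing at the full closure count, until either side would lose the
knot (a side survives a single discordant call by looking one residue
further — closure statistics at the boundary are binomial and a lone
flip should not stop the search). Entries overlapping the refined core
are removed and the search repeats, so two sequential knots yield two
disjoint cores. During refinement the interval must keep the *same*
label it started with: an over-trimmed interval can close into a
spurious different knot, and such calls terminate the trim rather than
extend it.

A chain is `composite` when at least two disjoint cores exist and their
invariant pairs multiply to the global pair — exactly the connected-sum
arithmetic of the Alexander determinant. It is `slipknotted` when the
global call is unknotted but some subchain is definitely knotted. Knot
depth is reported as the raw residue distance from each core boundary to
its terminus; no "deep/shallow" threshold is imposed.

Two approximations are deliberate: slipknot detection is anchored on the
fingerprint grid (a full single-residue quadratic scan is far beyond
desk scale), and core boundaries inherit the stochastic fuzziness of
closure at +-2-3 residues.

## The architecture screen

The screen mirrors the indirect search for doubly knotted proteins: a
registry maps domain families to their entanglement class and minimal
knotted-core length (the shortest knotted region seen among the family's
structures, `buildRegistry()`). A protein is a candidate when its
domains contribute an expected knot count of at least 2 and the chain is
long enough to hold those knots (sum of the qualifying
`min_core_length x knots_per_domain`). `knots_per_domain` handles
families where two consecutive domains form one knot together (0.5 per
domain; four such domains are needed for a double knot — this is what
makes a four-domain transporter architecture a candidate). The homology
gate then keeps candidates whose best hit against knotted structures has
e-value strictly below 1e-3; proteins with no hits at all are flagged,
not rejected, since a missing search result disproves nothing. Gene
pairs are classified as separated / adjacent / overlapping / fused, with
the adjacency cutoff at 50 nt by default — exemplar genomes show gaps of
~10 nt versus thousands, so any cutoff in between behaves identically on
real cases; it is exposed as a parameter.

## Buried interface area

For a two-partner complex, `interfaceB()` reports
`B = SASA1 + SASA2 - SASA12` with solvent-accessible areas from
Shrake-Rupley sampling: 960 deterministic Fibonacci-lattice points per
atom on the probe-expanded sphere (probe 1.4 A, NACCESS-style radii,
C 1.87 / N 1.65 / O 1.40 / S 1.85 / P 1.80 / H 1.00, default 1.80 A).
The exact Lee-Richards slicing scheme is not reimplemented: any
consistent SASA satisfies the buried-area identity, and the sampling
error is bounded against closed-form sphere oracles (< 1% for an
isolated atom, < 2% for two intersecting spheres) in the test suite.
The lattice is oriented in a molecule-attached principal-axes frame
(signs fixed by third moments), so areas are invariant under rigid
motions to numerical precision; when the principal values are degenerate
the lab frame is used and invariance holds only to the sampling
tolerance.

## Synthetic ground truth

All tests run on generated data with known topology:

- **Closed curves**: (2,q) torus parametrizations (q = 3, 5), the
  trigonometric figure-eight, and polygonal braid closures for 5~2~ and
  6~1~ (nested coplanar return arcs guarantee the closure adds no
  crossings; words with more than one closure component are refused).
  Geometry is protein-like — about 3.8 A between consecutive points.
- **Open planted cores**: an overhand knot threaded on a straight rope,
  built as a double pass through a three-crossing two-strand braid with
  a return arc beside it. Its crossings are localized, so any interval
  containing the body is knotted and any interval truncating it is not,
  and the termini leave at opposite ends of the body. Two bodies
  threaded on one rope give the composite fixture. (An opened torus
  curve is unsuitable here: its strands keep a constant 8 A separation,
  and its open form survives trimming of 10-15 residues, so planted
  boundaries could never be stated to +-5 residues.)
- **Planted truth**: the ground-truth core interval is the minimal
  knotted subchain of the *noiseless* template, measured once per body
  size by the generator itself (alternating single-residue trimming
  under a fixed internal seed, cached). This is deliberate: the minimal
  core under stochastic closure ends a few residues inside the
  outermost crossings, and that offset is a property of the template
  geometry, not of any particular noisy realization.
- **Slipknots**: the rope completes a trefoil loop (epsilon gap), makes
  a short retractable out-and-back excursion (so knotted prefixes end
  well outside the hull and are called with high support), then retraces
  45% of the loop 1.6 A outside it — undoing the knot for the full
  chain.
- **Tables**: `makeAnnotationFixture()` plants the five doubly knotted
  architectures among decoys that carry at most one entangled domain or
  are too short; `makeGeneFixture()` realizes the four genomic layouts
  (gap of 4000 nt, gap of 11 nt, overlap of 7 nt, one fused ORF).

Coordinate noise defaults to 0.2 A (Gaussian, per coordinate); planted
labels are stable well beyond that, but above roughly 1 A the closure
support of shallow features degrades and the planted-boundary guarantee
no longer holds. The generators emulate backbone geometry and topology
only — no side chains, no sequence, no physical energetics — so passing
tests demonstrate the correctness of the topological machinery, not
performance on experimental structures with missing residues or
low-confidence segments (those are the job of the C-alpha gap logging
and the mean-pLDDT gate, default threshold 70, advisory and
overridable).

## Numerical choices

- KMT piercing tolerance 1e-9 (relative to the coordinate spread);
  degenerate triangles are removable, ambiguous intersections are not.
- Projection retries: 25 Fibonacci-sphere directions; crossing
  degeneracies (vertex hits, equal heights, collinear overlaps) and any
  failure of the `|Δ(1)| = 1` check move to the next direction.
- Exact arithmetic: two-prime modular interpolation with symmetric
  lift; a lift mismatch (coefficient beyond ~2^30) is treated as a
  degenerate projection. `det2` evaluation is guarded against exceeding
  exact double-integer range.
- Problem sizes used by the acceptance script: 100 noisy closed knots
  for the KMT check, 40 planted-core fixtures (alternating single and
  composite), 200-decoy screen tables; the test suite runs the 100-chain
  recovery sweep.

## Limitations

- Knot labels cover the unknot, 3~1~, 4~1~, 5~1~, 5~2~, 6~1~, 6~2~,
  6~3~ and 3~1~#3~1~; any other invariant pair is reported as
  `unresolved(det1,det2)` rather than forced into the table.
- No chirality calls, no HOMFLY/Jones polynomials, no links between
  chains, and no nested knot-within-a-knot search.
- Stochastic closure makes boundary-adjacent subchain calls genuinely
  marginal; reported core boundaries carry a few residues of
  uncertainty by nature, not by implementation accident.
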