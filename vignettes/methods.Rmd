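---
title: "Landscape-explicit dispersal routing: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape-explicit dispersal routing: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tardis)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The README shows the surface; here we document
the model assumptions, the numerical conventions, and the places where the
design was genuinely open.

## The spatiotemporal graph

A palaeogeographic history enters as a stack of elevation rasters, each
with an absolute age (Ma) and a land–sea mask (by default, elevation
≤ 0 m is ocean — the mask a DEM itself implies). Within a layer, every
unmasked cell is a vertex and adjacent unmasked cells are joined by an
undirected edge whose weight is the great-circle distance between cell
centres on a spherical Earth of radius 6371 km, extended by Pythagoras for
the elevation difference. We deliberately use a sphere, not an ellipsoid:
at the 1°–10° grids this framework targets, ellipsoidal corrections are
second-order relative to cell discretization. Queen's case (8 neighbours)
is the default adjacency because rook's case forbids diagonal movement and
inflates path lengths anisotropically. Global grids additionally wrap
across the antimeridian; there is no wrap across the poles, so routes
cannot shortcut through the polar singularity.

Cell bookkeeping is fixed and documented: 0-based row-major cell ids, row
0 at the northern edge, longitudes half-open from −180°. All exported
tables use these conventions.

Masking can strand "islands" of connected land. Two linking policies are
provided. Degree-1 linking iteratively merges the two components whose
closest vertex pair (by great-circle distance, exhaustively searched) is
globally smallest — a minimum spanning tree over islands, adding exactly
`n_islands − 1` flagged edges. Degree-k linking adds up to k closest
cross-pairs per island pair, optionally suppressing island pairs whose
connecting great-circle segment passes through a third island (the
segment is sampled at half-cell resolution and tested against island
membership — an approximate, resolution-limited intersection test, which
is why it is exposed as an option rather than a default). Island links are
weighted by great-circle distance only — the gap is open ocean, so an
elevation term would be meaningless — times a configurable multiplier
(default 1) for users who want sea crossings penalized.

Layers are chained oldest→youngest by *directed, zero-weight* temporal
edges between homologous cells; a per-layer-pair homology table (e.g. from
a plate-rotation model) redirects them, identity being the default.
Masked cells receive no temporal edges, and assembly fails loudly if any
consecutive pair would end up with none, because a path could then never
cross that time boundary. The temporal subgraph is a DAG by construction:
no route can revisit an older layer.

## Climate space

The 19 standard bioclimatic variables are computed per cell from monthly
climatologies under the ANUCLIM conventions: monthly mean temperature is
`(tmax + tmin)/2`; quarters are consecutive 3-month windows with
December–January wraparound and ties broken by the earliest start month;
seasonality (bio4, bio15) uses the sample (n−1) standard deviation, with a
population-sd switch for users matching other implementations.
Isothermality (bio3) is NaN when the annual temperature range is zero;
it is also the default member of the unconditional drop list because its
ratio form is fragile at low temperature ranges.

Redundancy among the 19 variables is removed by hierarchical clustering
(complete linkage — the most conservative standard choice for "everything
in this cluster is highly correlated"; configurable) on the `1 − Pearson r`
distance, cut at height 0.3, i.e. r = 0.7. One representative survives per
cluster, preferring monthly-scale variables (bio1–bio7, bio12–bio15) over
quarterly composites (bio8–bio11, bio16–bio19) because monthly extremes
carry the physiologically limiting conditions, then the lowest bio number
for determinism. The pipeline additionally excludes variables with zero
variance across tips before clustering — constant columns carry no
information for a climate space and would otherwise abort the run (the
low-level `select_variables()` treats them as an error, naming the
column).

The climate space itself is a PCA of the tip conditions with centring and
unit-variance scaling — the variables mix °C, mm and dimensionless ratios,
so unstandardized PCA would just rank them by unit size. All axes are
retained: projection is then an isometry of the standardized space, and
distances in PC space equal distances among standardized conditions.

## Niche-constrained least-cost routing

Each branch defines a straight segment in PC space between the ancestor
and descendant niche positions — the gradualist reading of a niche shift.
A two-point "regression line" through two points is that segment; we keep
the name "niche line" and note that the open question is not the line but
the residual: residuals are measured to the *clamped* segment by default
(`clamp = TRUE`), so climates beyond either endpoint are penalized by
distance to the nearer endpoint. The unclamped infinite line is available
because neither convention is obviously right; clamping is the default
because the segment models the shift actually implied by the two
reconstructed states, not its extrapolation.

An edge's climate is the arithmetic mean of its two endpoint cells'
selected variables, using the layer the edge lives in (a horizontal edge
exists within one time slice). The climatic weight is the *squared*
residual — species' responses to deviation from a climatic optimum are
conventionally modelled as quadratic, and squaring also makes the weight
smooth at zero.

Compounding: climatic and topographic weights are each rescaled to [0, 1]
and multiplied. The rescaling divides by the set maximum rather than
min-shifting. This is deliberate and load-bearing: the graph's weight set
includes the zero-weight temporal edges, so the set minimum is zero and
"rescale to [0, 1]" degenerates to division by the maximum. Subtracting a
positive per-edge minimum would silently re-rank path totals by hop count
and break the guarantee that, under spatially uniform climate, the
compound least-cost path is the topographic least-cost path. Division by
the maximum preserves path ordering exactly; a constant nonzero component
rescales to all-ones (the multiplicative identity), and an exactly-zero
residual stays exactly zero, so a compound weight is zero precisely when
the edge's climate lies on the niche line. The standalone
`rescale_unit()` utility keeps the conventional `(v − min)/(max − min)`
form for general use.

Paths are found with Dijkstra's algorithm (igraph's C implementation) on
the directed graph. Zero-weight edges are legitimate — time passage is
free, and on-line climates cost nothing — so equal-cost path sets are
common, and we make the result deterministic rather than epsilon-inflating
weights: among minimum-cost paths we take the one with fewest hops, then
the lexicographically smallest vertex-id sequence. Implementation:
distances from the start and to the end identify the shortest-path DAG
(edges with `d_start(u) + w + d_end(v) = cost`, relative tolerance 1e-9),
a BFS on that DAG gives minimum remaining hop counts, and a greedy walk
always takes the smallest-id successor that still completes in minimum
hops. Anchor ages map to layers by midpoint intervals closed at the older
end (a stage-level layer represents an interval; an age exactly on a
boundary belongs to the younger layer), and anchor coordinates snap to the
nearest land cell with exact ties broken by lowest cell id.

Geographic path length is always measured on the stored topographic
weights, never the search weights — search and measurement are separated
so that changing the climatic scheme changes *which* route is found but
never how long a given route is. Rates are length divided by branch
duration (km/Myr).

## Ancestral states, disparity, stratigraphic fit

Ancestral climatic tolerances are reconstructed per variable under
Brownian motion by generalized least squares on the tree covariance: the
root is the GLS mean, internal nodes are conditional expectations given
the tips, and 95% intervals use the REML rate estimate (n−1 denominator)
with a prediction variance that includes root-estimation uncertainty. The
two-tip equal-branch case reduces to the tip mean, and the implementation
is cross-checked in the tests against an independent re-rooting
implementation (phytools::fastAnc) and a direct matrix solve. Each
variable is treated independently; correlated-trait reconstruction is out
of scope.

Lineage states are linearly interpolated along branches at 0.1-Myr steps
from the older endpoint, with the younger endpoint always appended; when
the step divides the duration the per-branch sample count is
`floor(duration/step) + 1`.

Climate-space occupancy is summarized by four standard disparity metrics —
sum of per-axis variances (n−1), sum of per-axis ranges, mean pairwise
Euclidean distance, displacement from the centroid — in contiguous 2-Myr
bins closed at the older edge, each bin bootstrapped (default 100
replicates, the parameter exposed because 1,000 is equally defensible) to
its own sample size, reporting bootstrap mean, median and percentile 95%
intervals. The bootstrap uses a self-contained Park–Miller generator
seeded per call, so results are bit-reproducible and the caller's RNG
state is never touched. Bins with fewer than two points yield NA for the
metrics that need two.

Stratigraphic fit: SCI is the fraction of non-root internal nodes whose
oldest descendant first appearance is not older than their sister
lineage's (polytomies: the sister set is all other children of the
parent). GER is `1 − (MIG − G_min)/(G_max − G_min)` with internal nodes
dated to their oldest descendant first appearance; `G_min` is the range of
first appearances and `G_max = Σ(oldest − FAD_i)`, the classical closed
forms for the best and worst topology for a given age set. On a pectinate
topology these extremes are attained by assignments of ages to tips, which
is how the tests verify them by exhaustive permutation. All-equal tip ages
make GER undefined; we return 1 with a warning.

Geographic ancestral-origin inference itself (random-walk MCMC on the
sphere) is consumed, not re-implemented: the package summarizes externally
produced posterior coordinate samples (1° binning, separable Gaussian
smoothing with longitude wraparound, Silverman's rule per marginal unless
a bandwidth is given, highest-density cell centre, marginal 95%
highest-density intervals) and classifies a posterior as unimodal when the
smoothed surface has a single strict 8-neighbour local maximum — one
plausible operationalization among several.

## The synthetic fixture

The generator produces everything the pipeline consumes with known ground
truth, and its defaults are the package's reference study conditions: a
10° global grid (18 × 36), four layers spanning 255–225 Ma, 30% land,
AR(1) terrain drift 0.9 (so homologous land persists between layers), and
a 32-tip tree. Terrain is a sum of low-frequency cosine waves (periodic in
longitude, so global grids wrap cleanly) thresholded at the land-fraction
quantile — smooth, seed-deterministic, and exact to the target fraction up
to cell discreteness. Climatologies are analytic: a quadratic
equator-to-pole gradient (28 °C equatorial mean, 45 °C equator-pole
difference), a 6.5 °C/km lapse rate over land, a seasonal sinusoid whose
amplitude grows with latitude (18 °C at the poles) in opposite hemispheric
phase, a diurnal range growing with latitude and elevation, and
precipitation as a tropical peak (220 mm/month) plus midlatitude belts
(90 mm/month) with mild wet-season modulation and optional Gaussian noise
(sd 5 mm/month) clamped at zero. With zero noise every field is an exact
analytic function, which is what the closed-form BIOCLIM tests exploit.
Trees come from a forward birth–death simulation (birth 0.25/Myr, death
0.1/Myr — net diversification comfortably producing a few dozen lineages
over 30 Myr) in which extinct lineages are retained as fossil-like tips,
pruned deterministically to the requested size; dispersal is a Brownian
walk on the sphere (400 km per √Myr) rejection-sampled against each
layer's land mask (after 200 rejections the point snaps to the nearest
land cell — a pragmatic guard for slivers of land), and climate traits
evolve by Brownian motion with known roots and rates.

What the fixture deliberately does *not* emulate: plate tectonics (drift
is statistical, not kinematic), atmospheric physics (climates are smooth
analytic fields without storms, orographic rain shadows or continentality
beyond the simple proxies), spatial sampling bias, and taxonomy. Passing
tests on the fixture therefore demonstrate the correctness of the graph,
weighting, routing and summary machinery — not that any particular
empirical reconstruction is right.

## Problem sizes and numerical tolerances

The test suite exercises the framework at sizes chosen to keep the full
suite under a couple of minutes while still being discriminating: 100
random masked two/three-layer graphs of ≤ 24 vertices for exhaustive
path-enumeration equivalence (equality at 1e-12 relative tolerance); 50
endpoint pairs on the uniform 1° global queen lattice for the geodesic
lower bound; 500 replicates of 64-tip trees for ancestral-state interval
calibration; 1,000 random path queries for temporal monotonicity; 10-degree
4-layer fixture runs for the end-to-end pipeline. Closed-form BIOCLIM
checks are asserted at 1e-9 and disparity oracles at 1e-12.

One geometric subtlety is documented rather than hidden: the classical
octile bound (path/geodesic ≤ ≈1.085 for 8-neighbour lattices) is a
planar result. On a spherical lattice the east–west cell width shrinks by
cos(latitude), the angular gaps between the eight step directions widen,
and near the poles the worst-case detour genuinely exceeds the planar
bound. The geodesic-bound checks therefore sample endpoint pairs uniformly
by area on the sphere — the natural meaning of "random locations on a
globe" — under which the bound holds; uniform-by-cell sampling would
concentrate half of all points poleward of 60° and violate it by
construction, telling you about polar grid anisotropy, not about the
router.

## Known limitations

Routing is deterministic least-cost: no stochastic path ensembles and no
circuit-theoretic (current-flow) connectivity. Weights are isotropic
(cost(a→b) = cost(b→a)) although the graph representation would support
asymmetry. The climate-residual scheme models the fundamental niche only —
no biotic interactions, no habitat suitability beyond climate. Posterior
origin summaries assume a single, externally estimated topology. Raster
I/O is plain-text (ESRI ASCII grids plus delimited manifests); NetCDF and
GeoTIFF readers would be straightforward additions where those libraries
are available. Finally, coarse grids quantize short dispersals to zero —
branches whose endpoints share a cell have zero geographic length by
construction, which inflates the zero mode of any rate distribution and
should be kept in mind when interpreting rates near the grid scale.
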