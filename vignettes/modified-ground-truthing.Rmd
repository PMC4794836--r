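---
title: "Modified ground-truthing: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified ground-truthing: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groundtruthr)
```

## The measurement problem

Commercial business listings are the dominant data source for food-environment
exposure measures, but in town and rural areas they are noisy in both
directions: stores that closed or never existed remain listed (phantoms), real
stores are missing (omissions), and some listed establishments are not food
stores at all (ineligible: institutional cafeterias, membership clubs, shops
that sell no food). Full ground-truthing — driving every street in the study
area and enumerating every outlet — is the accepted gold standard for
correcting these errors, but it is expensive: most of the mileage is spent on
roads with no retailers.

The modified protocol this package simulates exploits the spatial structure of
small-town retail: nearly all stores sit in a few *central commercial
clusters*, so canvassing only the streets inside a buffer around those
clusters recovers almost all of the information at a fraction of the mileage.
The clusters are built **from the listing alone**, so the canvass plan exists
before any field visit; zone membership never peeks at the census. Stores
listed outside the clusters are not visited; they are handled by one of two
bracketing assumptions — all open (maximises sensitivity, keeps phantom false
positives) or all closed (forfeits a little sensitivity, makes false positives
structurally impossible).

## Quantities

For one site and one candidate list, judged against the ground-truthed census:

* **TP** — listed stores verified open and eligible ("open/found");
* **FP** — listed records not found, closed, or ineligible;
* **FN** — open eligible stores absent from the list ("new stores");
* **PPV** = TP / (TP + FP), **sensitivity** = TP / (TP + FN), both undefined
  (NA, never 0) when their denominator is zero.

Site-level values are aggregated by **macro-averaging** (the mean of per-site
values), which is the convention for multi-site validation studies;
pooled-count metrics differ (pooled sensitivity of the three-site reference
counts is 90/136 = 0.66 against a macro mean of 0.62) and are a different
estimand, so the report tables show macro means.

Matching a listing record to a census store follows the field protocol's
three tiers: *exact* (normalized names equal), *close* (token-set name
similarity — an owner's name prefixed to a store name still scores 1), and
*lenient* (same category code within the distance gate, which captures
franchises listed under their operating company). All tiers require spatial
proximity (`max_match_distance`, default 150 m, standing in for "near the
same intersection"); matching is a greedy partial bijection ordered by tier,
then distance, then record id, so it is deterministic. The defaults
(similarity 0.85, 150 m) are design choices, exposed in `match_policy()`; no
published values exist for them. On synthetic data the `"id"` policy uses the
generator's linkage directly and is exact by construction.

## Cluster zones

A *central commercial cluster* is any group of at least two listed stores
whose buffers form one connected canvass area. Two listed stores are linked
when their distance is at most `linkage_distance`; the default is twice the
buffer radius, i.e. exactly the condition under which their buffers touch.
The buffer radius defaults to 200 m (the stated round figure for an eighth of
a mile; `201.168` gives the exact conversion, and 1 mile = 1609.344 m
throughout). Both knobs are exposed because the linkage rule is a genuine
design choice: published protocol descriptions do not define "cluster"
operationally.

Zone geometry is **exact**, not polygon-approximated. Because every zone is a
union of equal-radius discs:

* containment is distance-to-nearest-member ≤ r (boundary inclusive);
* area comes from Green's theorem applied to the exposed boundary arcs of
  each disc (holes handled automatically by arc orientation);
* road mileage inside zones clips each segment against each disc by solving
  the entry/exit quadratic and merging parameter intervals.

Polygons are produced only when exporting zones to GeoJSON, at 64 vertices
per quarter circle (sub-metre error at r = 200 m). This is why the test suite
can hold geometric checks to analytic closed forms rather than approximation
tolerances.

One structural note: as radius or linkage grow, the set of clustered stores
and the total zone area are monotonically non-decreasing, but the zone
*count* is not — two lone stores beyond linkage range form no zone, then one
zone once the linkage reaches them.

## The two scenarios

`simulate_modified()` assumes canvassing a zone finds every open store on its
streets — driving a street either finds a storefront or it does not, and the
protocol treats detection as certain; no detection-noise model is offered.
The validated list is therefore

* *verified*: every open eligible census store inside any zone, **including
  unlisted stores discovered during the canvass** (this is forced by the
  accounting: the modified scenarios recover more true positives than the raw
  list, which is only possible if the canvass adds new in-zone stores);
* *assumed* (only under `assume_open`): every out-of-zone listing record,
  kept unverified. Out-of-zone phantoms and ineligible records are
  indistinguishable here — both are false positives either way — and are
  treated identically.

Two invariants follow structurally and are enforced by tests on randomized
sites: `assume_closed` has FP = 0 (hence PPV = 1 whenever TP > 0), and
TP + FN equals the census open-eligible count for every list built over the
same census.

## The synthetic generator

`synth_config()` defaults describe one town/rural site as the analysis
assumes it: two town centres with street grids and sparse rural connectors;
40 clustered open stores (per-axis Gaussian dispersion 150 m around the
centres, so distance-to-centre is Rayleigh) plus 3 isolated ones (7 % of open
stores); listing omission probability 0.34; 14 in-cluster and 3 isolated
phantoms plus 2 ineligible establishments, which makes bad records ~40 % of
the listing and ~44 % of the census size; coordinate jitter 15 m; listed-name
noise 15 %. That yields ~47 listed records per site, inside the 45–150 range
typical of such sites. Isolated placements keep at least
`isolation_min_separation` (1000 m, comfortably more than twice the default
buffer radius plus jitter) from every other store so that, under default
zoning, they are singletons and never seed a zone; the separation value is a
package choice, since only the "≥ 2 × dispersion from centres" rule is given
by the protocol description. All coordinates are planar metres in an abstract
projected frame — at study areas of a few kilometres, geodesic distortion is
immaterial.

Each generator stage seeds its own stream from `seed` (+0 roads, +1 census,
+2 listing), so a stage rerun standalone reproduces the run exactly; the
pipeline derives per-site seeds as `seed + 1000·(site − 1)`.

What the generator does **not** emulate: real street topology, geocoding
error correlated with rurality, store-type-dependent listing accuracy, and
temporal dynamics (stores opening/closing between listing and field dates).
Passing tests on synthetic sites therefore demonstrate the pipeline's
accounting and geometry, not the field accuracy of any particular commercial
vendor's list.

## The deterministic reference fixture

`make_reference_fixture()` builds three sites (A, B, C) whose six strata —
listed-open in/out of zone, bad listing in/out, new store in/out — are the
unique values consistent with the reference confusion counts in
`reference_confusion_counts()` under the identities

```
loo = TP(open) − TP(closed)     no = FN(open)      bo = FP(open)
loi = TP(raw) − loo             bi = FP(raw) − bo  ni = FN(raw) − no
```

The geometry makes zone construction recover the intended partition exactly:
in-zone records sit on a 60 m grid (one linked cluster, all within 200 m of a
member), every out-of-zone record sits on a ring 4 km from the cluster with
pairwise gaps over 1.5 km (singletons, never in any zone), and new out-of-zone
stores sit on an offset 4.5 km ring. The per-site split of "not found" versus
"ineligible" among the bad records is not recoverable from published totals,
so the fixture records all of them as not-found; the distinction changes no
metric. This fixture is a synthetic stand-in constructed from published
summary counts — the original field coordinates were never published — and is
labelled accordingly.

```{r}
res <- evaluate_site(make_reference_fixture("B"))
res$confusions
```

## Cost model

`cost_report()` works in statute miles and dollars: canvass miles are either
measured (odometer inputs) or estimated as road miles × a back-tracking
factor (default 1.27 — covering a network requires repeated passes); transit
miles are trips × round-trip miles; dollars are miles × rate (default
$0.565/mile, a standard institutional reimbursement rate). All arithmetic
uses unrounded values; `render_cost_table()` rounds once at display time
(half-up: whole miles, whole dollars, whole percent; accuracy metrics to
2 dp). Per-site cells rounded independently can therefore differ by a mile
from rounded totals; computing from unrounded values and rounding once is the
deliberate convention. Time and staffing costs are out of scope: the canvass
speed inside commercial clusters differs from open-road speed, so no honest
hourly estimate is available for the modified protocol.

## Numerical and degenerate-input choices

* Undefined metrics (zero denominators) propagate as NA and render as "NA",
  never as 0.
* Duplicate disc centres are deduplicated before arc bookkeeping; tangency
  (distance exactly 2r) contributes a zero-width covered arc and is ignored.
* Empty listings produce no zones; `assume_closed` on no zones yields an
  empty validated list, zero TP/FP, and FN equal to the census size.
* Isolated/out-of-zone placement uses rejection sampling with a retry cap
  (default 1000); an unsatisfiable constraint raises an error naming it
  rather than degrading silently.
* Unresolved matching ties break by lexicographic id so every run is
  reproducible.

## Problem sizes used in the checks

The bundled checks run at desk scale: the three fixture sites (14–74 listed
records), randomized replicate batteries of 200 small sites (~25 stores
each) for the structural invariants, 500 seeded replicates of the default
single-site generator for the omission-rate calibration (mean omitted
fraction within three standard errors of 0.34), and grid-versus-disc analytic
cases for the geometry. These sizes were chosen so each property is exercised
well past its failure modes while the whole suite stays interactive.

## Known limitations

* Canvass detection is perfect by assumption; no partial-detection model.
* The generator's road networks are stylised grids; mileage figures from
  synthetic runs are illustrative, not calibrated to any real road database.
* Accuracy is not broken down by store type, although listing accuracy is
  known to vary by type; the category taxonomy is synthetic.
* Displayed cost tables inherit the single-rounding convention above; users
  comparing against hand-rounded per-site figures should expect ≤ 1-mile
  cell differences.
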