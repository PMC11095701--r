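---
title: "Methods: from BLE proximity pings to care-home social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from BLE proximity pings to care-home social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecontact)
```

## The measurement problem

Residential care homes are relational systems: the quantity, duration and
spread of face-to-face contact between residents, permanent staff and
agency staff shapes both care quality and infection risk. Bluetooth Low
Energy (BLE) wearables measure this directly. Each wearable periodically
scans for its neighbours and records a *sighting*: the two device IDs, a
timestamp, and the received signal strength (RSSI, in dBm) — a proxy for
distance. Stationary location markers are sighted the same way, which
localizes contacts to rooms.

`carecontact` converts such sighting streams into the objects a
quality-improvement or infection-prevention team actually reasons about:

1. **Interaction episodes** — maximal runs of proximate sightings of one
   dyad;
2. a **weighted undirected contact network** — people as nodes, tie
   strength as episode counts;
3. **SNA metrics** — degree, weighted degree, closeness, betweenness,
   eigenvector centrality, clustering, density, Freeman centralization,
   role assortativity;
4. **subcommunities** — Louvain modularity partitions;
5. **report tables** — strength/duration summaries, centrality by home
   and role, a role-pair contingency of long interactions, unique-partner
   counts, hour-of-day and location profiles.

Because real resident-level data cannot be shared, the package also ships
a ground-truthed synthetic care-home simulator, which is what all tests
and the acceptance script run against.

## Proximity filtering

The deployed system's convention is that an RSSI threshold of −75 dBm
separates "within about 1.5 m" from "further away". Radio physics says
signal *strength decreases* with distance, so the default rule keeps dyad
sightings with `rssi >= -75` (stronger than threshold = closer). Field
descriptions of such thresholds are sometimes written the other way
around ("RSSI < −75 indicates less than 1.5 m"), which is consistent only
with a device-specific scale; since this cannot be settled from data
dictionaries alone, the comparator is configurable
(`rssi_keep_rule = "weaker_than_threshold"` mirrors the rule). Location
sightings are never filtered: a weak marker ping still says where someone
was. Filtering is idempotent and order-preserving, and malformed input
rows are collected into a rejects report rather than silently dropped.

## Sessionization

Per canonical dyad (IDs sorted lexicographically — proximity data are
symmetric, so the pair is unordered), sightings sorted by time are merged
while the gap between successive pings is at most `max_gap_s` (default
60 s); a strictly larger gap starts a new episode. The episode starts at
its first ping and ends at its last, so a single-ping episode has
duration zero — there is no evidence of contact beyond the instant, and
crediting it with a scan interval would inflate durations. Hardware of
this class scans every few tens of seconds, making 60 s roughly two
missed scans; the parameter is exposed for other cadences. Merging is
invariant to input row order, partitions the pings exactly
(`sum(n_pings)` equals the input row count), and doubling the gap can
only reduce the episode count.

An episode's location is the modal marker among both devices' location
pings inside the episode window widened by one gap on each side, ties
broken toward the earliest-seen marker, `"unknown"` if there are none.

"Long" interactions are those **strictly longer** than
`long_interaction_min` (default 2 minutes; an inclusive rule is
available). With a 20 s scan cadence a detected duration is the true
duration floored to the cadence, which matters when validating long
counts against simulator ground truth.

## The contact network and its metrics

One node per rostered person (isolates retained — a resident with no
contacts is a finding, not a missing value), one edge per dyad with at
least one episode in the analysis window. The edge weight is the
**episode count**; total contact minutes, ping counts and mean RSSI
travel alongside as edge attributes, so analyses preferring a different
weight definition can rebind it.

Conventions, chosen to match how such data are read in practice:

* **Degree** is raw partner counts, not normalized: reported means like
  "39 connections" in populations of 30–110 are counts.
* **Shortest paths are unweighted hops.** Weights here encode tie
  *strength*; treating 1/weight as a length is available but off by
  default.
* **Closeness** defaults to *harmonic* closeness normalized by `n − 1`,
  because agency staff who attend rarely make real contact networks
  disconnected, where the classic `(n−1)/Σd` form degenerates; the
  classic form is provided for connected graphs.
* **Betweenness** is Brandes-style, unnormalized, each unordered pair
  counted once, equal-length geodesics split evenly.
* **Eigenvector centrality** is the Perron vector of the weighted
  adjacency by power iteration (tolerance 1e−9, L2-normalized). A
  positive diagonal shift (0.1 × max strength) breaks the ±λ eigenvalue
  tie that makes plain power iteration oscillate on bipartite graphs; it
  leaves the eigenvectors unchanged. An edgeless graph is an error — the
  quantity is undefined.
* **Density** is `2E/(N(N−1))` (0 when `N < 2`); **centralization** is
  Freeman's `Σ(k_max − k_i)/((N−1)(N−2))`; **clustering** is the local
  unweighted coefficient with 0 for nodes of degree < 2;
  **assortativity** is Newman's categorical coefficient on roles.
* **Reciprocity is deliberately not computed.** BLE proximity is
  symmetric by construction, so the networks are undirected and tie
  reciprocity is unmeasurable; `reciprocity_contact()` raises an
  explanatory error rather than returning a misleading number.

## Community detection

`louvain_partition()` maximizes weighted modularity

$$Q = \sum_c \left[ \frac{w_{in,c}}{m} - \gamma\left(\frac{s_c}{2m}\right)^2 \right]$$

with the two-phase Louvain scheme: greedy single-node moves to the
neighbouring community with the largest gain (ties to the smallest
community label), then aggregation into supernodes, until no move
improves Q by more than 1e−12.

Greedy growth from singletons is scan-order dependent and can lodge in
local optima that need compound moves to escape. The search is therefore
repeated deterministically: eight fixed scan orders (sorted ID, reversed,
by increasing/decreasing strength, plus four permutations from a private
RNG seeded by the `seed` argument), each followed by a refinement pass
restarting local moves from the found partition; then a
merge-two-communities-and-refine loop run to a fixpoint; then sixteen
coarse random-partition restarts from the same private RNG. The best-Q
partition wins. The result is a pure function of the network, the
resolution and the seed — repeated calls are identical, and the caller's
RNG state is untouched. In validation against exhaustive search over all
set partitions, this procedure attained the global optimum on every one
of 800+ random graphs with up to 8 nodes; the test suite asserts a
conservative ≥ 0.97 × optimal bound.

Edgeless networks partition into singletons with Q = 0 by convention.
Per-community density is the induced-subgraph density, 0 for singleton
communities.

## The synthetic care home

`simulate_home()` generates the sighting stream of one home with known
ground truth. Defaults describe a small nursing home — 12 residents and
19 permanent staff (a realistic small-home census), one 08:00–20:00 day
shift, and 14 simulated days; populations up to ~110 and longer horizons
are just parameter changes.

**Episode process.** Each dyad's interaction episodes follow an
inhomogeneous Poisson process with piecewise-constant rate

> base rate(role pair) × handover boost × midday boost × within-unit bias

The real generative process of a care home is unknown; a
stationary-within-window Poisson process is the simplest model with the
right first-order structure. The `rate_matrix` entries are **expected
episodes per dyad per hour of joint presence**. Staff dyads interact
only inside shift windows; residents are available 07:00–22:00 (a waking
day — simulated homes have no night-time contact). Handover boosts
(default ×3 in 30-minute windows at shift start, middle and end) apply to
staff–staff rates, reproducing the triple daily spike characteristic of
8am–8pm shift patterns; a midday boost (default ×1.5, 10:00–15:00)
applies to all staff-involving pairs, reproducing the busy core of the
home day. Agency staff attend each day with probability 0.3 (their
sparse, irregular presence is what drives their low degree in real
homes), and planted care units multiply within-unit rates by
`within_unit_bias`.

Episode counts per dyad-day are drawn exactly Poisson; drawn episodes
are then placed by sampling starts from the piecewise rate density and
sweeping forward, pushing any episode that would start within
`min_separation_s` (default 180 s) of its predecessor to the right and
dropping it only if pushed past the day's window. This keeps realized
counts essentially Poisson at realistic occupancies (the rate-recovery
tests confirm realized counts stay within 3√Λ of expectation) while
guaranteeing that distinct true episodes remain distinct after
sessionization — the property that makes exact truth-recovery tests
possible at zero miss probability.

**Durations** are log-normal per role pair (default medians 8–10
minutes, the merged-episode regime of real homes). **Locations** are
sampled with staff-staff contacts biased toward staff areas and other
pairs toward communal areas.

**Emission.** An episode emits dyad pings at exact `ping_interval_s`
cadence from start to end inclusive (a 10-minute episode at 60 s cadence
gives 11 pings), each dropped independently with `ping_miss_prob`. RSSI
follows the log-distance model
`rssi = rssi_at_1m − 10·exponent·log10(d)` with one contact distance per
episode drawn uniform(0.3, 1.5) m, per-ping Gaussian noise, and integer
rounding as BLE radios report. The default model (−66 dBm at 1 m,
exponent 4 — the upper end of the indoor path-loss range, standing in
for walls and bodies — noise SD 3 dB) is calibrated so the −75 dBm
threshold sits at ≈1.7 m: contact-range pings pass the filter and
optional decoy pings at ≥3 m fail it, with margin on both sides. Both
devices also ping the episode's location marker at the same cadence.
Timestamps are simulated local clock time without daylight-saving
transitions, emitted as ISO-8601 with a +0000 offset.

**Determinism.** All draws happen in a fixed order from the single
configured seed, so identical configurations give byte-identical CSV
output.

**What the simulator does not emulate** — and what passing recovery
tests therefore do not establish about real data: visitor churn, device
battery failure and systematic (non-independent) scan loss, multipath
RSSI structure (walls make noise non-Gaussian and non-stationary),
multi-person gatherings (an activity session appears only as its
pairwise decomposition), seasonal and weekday/weekend structure, and
transmission-relevant behaviour during contact. Recovery results say the
*pipeline* is faithful to its own model of the data, not that the model
exhausts reality.

## Report tables

Quantile-based summaries (medians, IQRs, 5th/95th percentiles) use
linear interpolation between closest ranks (R quantile type 7), with
IQR = Q3 − Q1 under the same rule. Percentages are printed to one
decimal. The long-interaction contingency table cross-tabulates the
ordered role pair of the canonical dyad; because canonical order is by
device ID, `(resident, staff)` and `(staff, resident)` cells are both
populated, and a symmetric-collapse option merges them. In the
three-category temporal views (res–res / res–staff / staff–staff),
agency staff fold into staff; they stay separate everywhere else. All
headline totals are computed from the data, never from roster
head-counts, since consented-wearer counts and employment rosters
routinely disagree in real deployments.

`run_pipeline()` writes every table as an unformatted CSV, a JSON
bundle, GraphML and GEXF network exports (GEXF for Gephi interchange)
and a manifest with input checksums, row/reject counts and the
thresholds used. Identical inputs and configuration yield byte-identical
outputs.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at sizes chosen to
exercise every code path while remaining quick to run: exhaustive metric
oracles on 200 random graphs of ≤7 nodes and modularity/Louvain oracles
on 50–100 graphs of ≤8 nodes (exhaustive search over all set partitions
is feasible only there); sessionization against a naive gap-scan oracle
on 500 random fixtures; and recovery runs on simulated homes of 8–40
people over 2–28 days — the 40-person, 14-day, within-unit-bias-20
configuration recovers planted units with ARI 1.0 and role-pair episode
counts within 3√Λ. Full-scale homes (≈110 people, 60+ days) are a
parameter change, not a code change.

## Known limitations

* Sessionization cannot distinguish one long contact with a gap in radio
  coverage from two short contacts; `max_gap_s` trades these errors.
* Edge weights count episodes; two homes with identical weights can
  differ greatly in contact minutes (exported alongside for that
  reason).
* "Doubling up" — two staff attending one resident — appears as two
  dyadic episodes; k-way interaction reconstruction is out of scope.
* Centrality on the undirected network cannot speak to who initiates
  contact, and no reciprocity measure is possible from this data.
* The pipeline describes structure; it performs no statistical inference
  (no ERGMs, no between-home tests).
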