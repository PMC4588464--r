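---
title: "Refining longitudinal establishment registries into density measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining longitudinal establishment registries into density measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bizscape)
library(dplyr)
```

## The problem

Commercial longitudinal business registries (NETS-style annual snapshots
derived from Dun & Bradstreet records, keyed by the nine-digit DUNS
establishment identifier) are an attractive source for measuring how the
local business environment — food stores, restaurants, physical-activity
venues, medical facilities, alcohol outlets — changes over decades. They
are also messy in specific, consequential ways:

* the files arrive as partially overlapping wide and long tables whose
  names vary between deliveries;
* one establishment accumulates several addresses over time (first,
  most recent, and the origin/destination of every *significant move* —
  a relocation where both the street address and the five-digit zip
  change), recorded with string-level deviations;
* delivery geocodes are least precise in the earliest years, so naive
  precision filtering differentially erases the early time series;
* the eight-digit SIC industry code a business reports can churn from
  year to year;
* co-located same-category records (one LLC per practitioner in one
  office) inflate naive counts.

`bizscape` implements a refinement pipeline for these data: address-book
construction, multi-provider geocode prioritisation, precision and
region filtering, planar projection with 10 m rounding, multi-year
categorisation, co-location collapsing, and per-geography trend
estimation — together with a synthetic registry generator that plants
known ground truth so every stage can be validated quantitatively.

## The pipeline, stage by stage

### Address book and year assignment

Every business contributes a `first` and `most_recent` address role; a
business with k significant moves adds `origin` and `destination` roles
per move, giving 2 + 2k roles and at most k + 1 distinct locations.
Comparisons run on a canonical form: upper case, punctuation stripped,
whitespace collapsed, street suffixes expanded through an editable
table (`street_suffix_table()`); the suffix table ships as data because
suffix dialects vary by region. Expected equivalences (first = origin
of move 1, destination k = origin k + 1, last destination =
most recent) are checked on the canonical form and logged — never
silently dropped — with the destination string preferred when versions
disagree.

The significant-move predicate is the conjunction: normalised street
address changed *and* zip5 changed. We normalise before comparing;
comparing raw strings would misclassify pure formatting changes
("10 Main St." vs "10 MAIN STREET") as street changes.

One location-role is assigned to each business-year. Snapshots are
annual, and the registry does not state whether a move-year observation
sits at the origin or the destination; we place the destination in
force from the move year itself onward, a documented convention
switchable via `boundary = "year_after"`.

### Geocoding, projection, rounding

Geocoding engines are pluggable providers returning candidate lists;
the package ships a deterministic mock provider that understands the
synthetic city's address grammar. Candidates merge under a fixed
a-priori priority — `gold_local` > `commercial_point` >
`commercial_street` > `vendor_supplied` — with deterministic tie-breaks
(source name, then (lat, lon)); the delivery-supplied coordinates are
the fallback of last resort. Precision labels form the ordered scale
point > block_face > street_segment > block_group > tract_centroid >
zip; block face is placed between point and street segment because a
block-face match localises to one side of one block. The default
analytic filter keeps "street level or higher" (point, block face,
street segment), and per-year exclusion reports make the early-year
differential visible.

Final coordinates are projected to UTM zone 18N on NAD83 (configurable
via `utm_crs()`) and rounded to the nearest 10 m per axis, ties away
from zero (the convention base-R `round()` would not give). The
projection is a Krueger-series transverse Mercator implemented
in-package and verified in the test suite against an independent
Snyder-formula implementation to well under 0.01 m. The 10 m grid is
what "same location" means downstream — it absorbs sub-10 m jitter
between engines while keeping genuinely distinct addresses distinct.
Study-region polygons (GeoJSON, or planar rings) exclude out-of-region
locations with a boundary-inclusive point-in-polygon test.

### Categorisation across years

Businesses map to mutually exclusive researcher-defined categories by
SIC sets (exact codes or prefixes), optional name include/exclude
patterns on normalised names, and optional size thresholds. A template
of 25 categories ships in
`system.file("extdata", "categories_template.yaml", package = "bizscape")`;
its SIC sets and thresholds are illustrative, not canonical — real
definitions are developed iteratively per study. Three mechanics
matter:

* **Priority ranks.** Mutual exclusivity needs a conflict rule; the
  lowest rank wins. Size-restricted definitions (large supermarket)
  rank above the residual categories they carve out of (convenience /
  small grocery), and name-driven definitions (multi-use venues matched
  by YMCA/JCC-style tokens) rank above SIC-driven ones.
* **Missing size fields fail threshold-bearing definitions.** A store
  with unknown employee count is never promoted to "large supermarket".
  Sales and employee values flagged as imputed upstream are used as-is
  by default; `strict_estimated = TRUE` treats them as missing.
* **The 75 % majority rule.** In overall mode a business keeps the SIC
  it reported in at least 75 % (inclusive: 3 of 4 qualifies) of its
  SIC-reporting years; otherwise the most recently reported SIC is
  used, since recent codes tend to be more specific and more likely
  corrected. The denominator is *reporting* years, not all active
  years — SIC can be missing, and a missing year carries no evidence
  about the business's type (switchable if a user prefers the stricter
  reading). Modal ties resolve toward the most recently reported of
  the tied codes, for the same recency rationale. Yearly mode instead
  reclassifies each business-year from that year's attributes.

MET banding for physical-activity venues follows the printed bands:
light/moderate for 1.6–5.9 METs, vigorous for ≥ 6. The bands as printed
leave (5.9, 6) unaddressed; we treat everything below 6 as
light/moderate so the banding is total. Values under 1.6 are sedentary
and rejected.

The SIC review-sampling helper reproduces the admission protocol for
candidate SICs: review all establishments when fewer than 50 report the
code in the reference year, a 20 % sample (rounded up) for 50–250, a
flat 50 above 250; an SIC is admitted when at least half the reviewed
sample is relevant (exactly half admits).

### Collapsing and counting

Records in the same category, same year, at the same rounded
coordinates collapse to one representative — the smallest DUNS number,
a documented convention chosen for determinism. Cross-category
co-locations always stay distinct (malls, medical office buildings).
Count tables carry raw and collapsed counts per geography × category ×
year with explicit zeros, so the choice between them is a sensitivity
analysis, not a preprocessing commitment. Per-series ordinary least
squares of count on calendar year (closed form, cross-checked against
`lm()` in the tests) gives the per-county trend lines; density
normalisation (per area, per capita) is left to the user, who can
divide by their own denominators.

## The synthetic registry

`generate_registry()` plants ground truth on a rectangular street grid
(40 positions × 30 named streets, 200 m spacing, rectangular zip zones)
placed inside UTM zone 18N at New York latitudes. Street names carry
abbreviated suffixes in the primary string and expanded suffixes in the
alternate, so normalisation is exercised on every address; moves always
change both street and zip zone, so every generated move is significant
by construction, and the two margins of the predicate are testable
separately with hand-built variants.

Defaults encode the documented error profile of a large metropolitan
registry: 21 annual snapshots 1990–2010; 10 % of multi-year businesses
with at least one significant move (a single-year business cannot move
between years, so the share among *all* businesses runs slightly
lower, about 8.5–9 %), with up to eight moves; delivery geocodes whose
zip-level-only share falls from 31 % (1990) through 16 % (2000) to 2 %
(2010), linearly interpolated; a per-reporting-year SIC deviation rate
of 0.0129, solved numerically against the generator's realised span
distribution so that roughly 7.7 % of businesses ever change reported
SIC (the realised share of businesses showing more than one distinct
code runs marginally below that, since coincident deviations to the
same code do not register); 5 % missing-SIC years; and a 15 %
co-location rate for categorized businesses, a value chosen once as
plausible for dense urban commercial clustering. The default category
mix covers eleven labels — every rule pathway in the template (pure
SIC, SIC prefix vs size threshold, name include, name exclude) — with
60 % of businesses uncategorized; the real-data share of uncategorized
businesses is higher (around 80 %), but at desk scale that would starve
the per-category tables that the collapsing and trend stages are meant
to exercise.

`preserve_majority = TRUE` caps deviations per business at a quarter of
its reporting years, so the true SIC always keeps an inclusive 75 %
majority — the planting condition under which overall categorisation
should recover every business. `plant_duplicates()` adds co-located
same-category records with suffix/punctuation-only name edits
(category-relevant tokens preserved), and records the collapse group in
the truth table, making `raw − collapsed` exactly predictable.

What the generator does *not* emulate: real address typos beyond string
versioning, non-significant relocations, geography calibrated to any
real region, NAICS codes, and category definitions with the fidelity of
real study definitions. Passing tests therefore demonstrate that the
*machinery* is correct — priorities, predicates, thresholds, grouping,
algebra — not that any particular real-world registry would be
processed without manual review.

## Numerical choices

* Rounding ties away from zero; documented because "nearest 10 m" alone
  does not fix the tie rule.
* Boundary points count as inside the study region; a business on a
  county line should not vanish from a 23-county study.
* The point-in-polygon test is an even-odd crossing rule with an
  explicit on-segment check (tolerance 1e-9 m); holes are handled by
  parity.
* Projection series are carried to fourth order in the third
  flattening; error inside a UTM zone is far below the 10 m grid.
* All randomness flows through explicit integer seeds; independent
  stages derive child seeds by a fixed affine map, so a pipeline run is
  bit-reproducible end to end.

## Problem sizes used in validation

The packaged tests validate recovery on 10,000-business registries
(about 67,000 business-years), oracle equivalences on 1,000-point
fixtures and all 15 geocode-source subsets, and 2-standard-error trend
coverage over 500 simulated 21-year series against a planted slope,
where the expected coverage of a ±2·SE interval with 19 residual
degrees of freedom is about 94 %. These sizes were chosen as the point
where binomial noise is small against the effects being checked.

## Known limitations

* Interpolation-based street geocoding, manual address re-matching and
  CASS-style standardisation are out of scope; real engines plug in as
  candidate providers.
* Name matching is pattern-based on normalised strings; registries
  record chains under many spelling variants, and the shipped patterns
  are starting points, not a registry-cleaning solution.
* The NAICS successor classification is not translated; crosswalks from
  SIC are lossy in both directions.
* The proprietary wide-file layout of a commercial delivery is modelled
  logically (column signatures, not byte layout); a real delivery may
  need a thin mapping step, supported via the dialect override in
  `read_registry()`.

## A minimal run

```{r, eval = FALSE}
params <- synth_params(n_establishments = 2000, seed = 1)
cfg <- pipeline_config(
  input = params,
  region = synthetic_region(),
  providers = default_mock_providers(seed = 1),
  out_dir = "run_out",
  seed = 1)
run <- run_pipeline(cfg)
run
glance(run)
tidy(run$trends)
autoplot(run$counts, trend = TRUE)
```
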