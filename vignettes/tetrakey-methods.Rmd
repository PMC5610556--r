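---
title: "Methods: morphometric intervals, key encoding, and synthetic fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric intervals, key encoding, and synthetic fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrakey)
```

## The identification problem

Workers of Indian *Tetramorium* are identified in two stages: a dichotomous
key places a specimen into one of 13 species groups from qualitative
characters (pilosity branching, antennal segment count, scrobe development,
sting appendage shape, gaster-base armament, eye reduction, clypeal and
spine characters), and within a group, species are separated by further
couplets and by 13 morphometric ratio indices computed from 14 linear
measurements. `tetrakey` encodes both stages as data plus a small set of
algorithms, so that the encoded keys, checklist, and type-series ranges are
editable without touching code.

## Morphometric model

Each index is `numerator/denominator x 100` over two of the 14 measurements
(OI = EL/HW, CI = HW/HL, SI = SL/HW, DMI = PW/WL, LMI = PH/WL,
PSLI = PSL/HL, PeNI = PTW/PW, LPeI = PTL/PTH, DPeI = PTW/PTL, PpNI = PPW/PW,
LPpI = PPL/PPH, DPpI = PPW/PPL, PPI = PPW/PTW). `compute_indices()` returns
raw values; an index is absent exactly when the numerator or the
denominator is unmeasured, so partially measured specimens remain
processable rather than erroring.

### Reporting precision

Descriptions print large indices as integers (CI 94) and small ones at one
decimal (PSLI 3.2). The printed formats never state the rule, so
`round_index()` implements the convention that reproduces all of them:
round half away from zero to the nearest integer; report that integer when
it is at least 10, otherwise report one decimal (half away from zero). The
threshold is applied *after* integer rounding: a raw ocular index of 9.615
reports as 10, matching the printed holotype OI of the inglebyi-group
species from the Andamans, while raw 9.44 reports as 9.4. Rounding uses a
relative tolerance of 1e-12 to absorb the binary representation of decimal
inputs (9.95 would otherwise round down).

### Rounding uncertainty and consistency

Measurements are recorded in mm to three decimals but printed at two. A
printed value v therefore only constrains the recorded value to
`[v - h, v + h]` with h = 0.005 mm (half of the last printed digit; use
0.0005 for 3-decimal data and 0 for exact values — the `h` argument is
exposed everywhere). For positive measurements the ratio is monotone
increasing in the numerator and decreasing in the denominator, so the
feasible interval of an index over the widened boxes is attained at
endpoint combinations:

`[(num_min - h)/(den_max + h), (num_max + h)/(den_min - h)] x 100`.

`index_interval()` errors if the widened denominator reaches zero, and
collapses to the raw index at h = 0. A unit test checks the endpoint
formula against an exhaustive grid search (step 1e-4 mm) on all 26 printed
holotype index/measurement pairs.

`consistency_check()` declares a printed index *consistent* when its own
rounding band (±0.5 for integers, ±0.05 for one-decimal values, read from
the printed string) intersects the feasible interval. Band intersection —
not point equality — is the right criterion because the printed index was
computed from unprinted 3-decimal data: naive 2-decimal recomputation
disagrees with the printed value for 14 of the 26 holotype indices of the
two Andaman species, yet all 26 are consistent at h = 0.005. All intervals
and bands are closed; boundary hits count as consistent, and in-range
checks in `match_specimen()` treat interval endpoints the same way.
Missing inputs yield the verdict `not_checkable`, never an error.

### Matching specimens to species

Only the two newly described species carry published worker ranges
(N = 2 and N = 6); `match_specimen()` therefore scores a specimen against
those and reports every other species `not_checkable` rather than guessing
ranges. The score is the fraction of checkable indices inside the
h-widened feasible interval of the species' range; candidates are ranked
by score with alphabetical tie-break.

## Key encoding

Each key is a JSON document (schema published at
`inst/extdata/keys/key-schema.json`): a character table (id, kind, states
or numeric domain, description, figure citation) and couplets of exactly
two leads, each lead carrying its verbatim text, a predicate in a small
grammar (equality, set membership, numeric comparison, and/or/not), and a
GOTO or terminal outcome. Because no JSON-Schema validator is available at
run time, `load_key()` performs an equivalent structural validation in R
(two leads per couplet, existing GOTO targets, declared characters only,
one outcome per lead) and reports violations with the couplet number.

Encoding decisions where the prose key bundles several characters into one
lead:

* The first-listed character of a couplet is authoritative for the
  predicate; the remaining states are *advisory* predicates whose conflict
  produces a warning, not a different route. This follows the sting-first
  reading of the species-group key's sting/frontal-carinae couplet and is
  applied uniformly (head shape at the cordate couplet, spine length at the
  final couplet, scrobe development at the 11-segmented couplet).
* Relative characters ("spines comparatively longer/shorter") are ordinal
  with an explicit `intermediate` state that satisfies neither lead; the
  eye-size couplet's numeric gap (ommatidia 7–9) is preserved as a numeric
  gap. `validate_key()` reports these as gap diagnostics; they are the only
  expected warnings on the packaged keys.
* The inglebyi-group key contrasts spine length twice, nested (couplet 2
  within its "relatively longer" branch again at couplet 4). One ordinal
  character cannot serve both contrasts, so at couplet 4 the presence of
  the large anteroventral peduncular lamella (listed in the same leads) is
  authoritative.
* The tonganum-group key retains *T. tonganum* (excluded from the Indian
  checklist) because the species is widespread in tropical Asia; the
  printed numbering of its leads is preserved in the lead texts while the
  structural encoding uses 4 couplets.

`traverse()` demands exactly one true lead per visited couplet and known
values for every consulted character; violations raise typed conditions
(`tetrakey_ambiguous_state`, `tetrakey_key_conflict`) that the CLI maps to
exit codes 2 and 3.

### Partial knowledge

`traverse_partial()` returns exactly the set of terminals reachable under
some completion of the UNKNOWN characters. It branches lazily on the value
of an unknown character the first time a couplet consults it, so a value
chosen on one branch stays fixed for the rest of that path; this is
equivalent to enumerating all completions (the test suite checks equality
against a brute-force enumeration oracle on all three keys) but explores
only consulted characters. A deliberate consequence: a *known* value that
satisfies neither lead (an ommatidia count of 8, an `intermediate` spine
state) is a conflict-flagged dead end contributing no terminals, because no
completion of the unknowns can route it. Users wanting the permissive
reading — "treat my intermediate observation as unresolved between the two
leads" — should record the character as UNKNOWN instead; we chose
completion semantics over silently widening known observations so that
`traverse_partial` has a single exact meaning, and so that adding knowledge
can never enlarge the terminal set (a tested invariant).

## Checklist and diagnoses

The checklist CSV mirrors the published species table (42 valid records
with endemic/exotic flags, plus 2 excluded records with reasons).
`fauna_summary()` computes totals solely from flags; the endemism rate
rounds half away from zero (27/42 → 64%). The source text counts "12
species groups" while naming 13 groups in its table and accounts; the
package reports `n_named_groups = 13` and records the discrepancy in the
data notes. The native-versus-exotic ambiguity of the two widespread
tramps in the bicarinatum group is kept as free-text comments; flags follow
the table exactly.

Group diagnoses are conjunctive predicates over the species-group key's
character vocabulary plus a complete template state vector per group. The
printed diagnosis of the mixtum group contradicts the key (it denies the
gaster-base horns that the key uses to reach the group); the encoding
follows the key and the group account's own comments, with the
contradiction documented in the packaged data notes. `apply_diagnosis()`
treats UNKNOWN permissively: a group is a candidate unless some known state
contradicts its predicate. The two `unclear`-group species are
non-diagnosable and never enter candidate sets. For all 13 groups, a state
vector built from the group's template traverses the species-group key to
that group — a tested invariant tying the two modules together.

The type-series data records two internal discrepancies of the jarawa
description (LPpI 86–87 and PPI 126–127 in the description text versus
87–91 (91) and 126–130 (126) in the measurement list); the packaged ranges
follow the measurement list and flag the description values under
`description_discrepancies` without guessing intent.

## Synthetic fixtures

`generate_specimens()` samples each measurement independently within the
published range — uniform by default, or a truncated normal at the midpoint
with sd = width/4 for a unimodal alternative. Independent sampling ignores
the allometric correlation of real ants (large heads co-occur with large
mesosomas); the fixtures exercise interval logic, not biology, so a green
recovery test establishes that in-range data scores 1.0, not that the
generator is a realistic morphometric model. Values are rounded to the
3-decimal recording convention.

Out-of-range rows displace one measurement (cycled over the fields) upward
beyond the range maximum. The displacement is the larger of 0.5 x range
width and the smallest displacement that provably pushes *every* index
involving the field outside the h-widened feasible interval for any
in-range partner values (computed from the ranges by the same ratio
monotonicity as above, with a 1e-6 relative safety margin). The floor
matters: several ranges have zero width (EL and PSL of the N = 2 species),
where 0.5 x width displaces nothing, and ratio slack can absorb a
half-width displacement of wide fields. Upward displacement keeps all
values positive. With this rule, perturbed specimens fail exactly the
affected index family — a tested invariant.

`generate_state_vectors()` instantiates a group's diagnosis template and
blanks each character independently with probability `unknown_rate`; with
rate 0 every vector traverses to its group, and with rate > 0 the target
group is always contained in the partial-traversal terminal set (both
tested). Both generators are deterministic given a seed and restore the
caller's RNG state.

## Numerical choices and limitations

* Closed intervals throughout; ties at band or interval boundaries count
  as consistent/in-range.
* Raw index identity is maintained to relative 1e-9; rounding uses a 1e-12
  relative guard against binary representation error.
* The dorsal petiole index (DPeI) is computed from the standard node
  width/length measurements even though, for nodes whose dorsum is narrower
  than the base, it overstates how broad the node appears; no alternative
  measurement is published, so none is implemented — the packaged data
  carries the caveat.
* Coordinates accept hemisphere-suffixed ("11.975817 N") and signed forms
  and normalize to signed decimal degrees; CSV dialect is fixed (UTF-8,
  comma, `.` decimal separator) to avoid locale drift.
* No probabilistic identification, no image-based measurement extraction,
  no external nomenclatural resolution.
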