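# tetrakey

Identification toolkit for workers of the hyperdiverse ant genus
*Tetramorium* in India, built for taxonomists and biodiversity
informaticians who work with specimen measurement tables and dichotomous
keys rather than images.

India currently holds 42 valid *Tetramorium* species in 13 named species
groups, 27 of them endemic (an endemism rate of 64%); two further names are
excluded from the fauna (a misidentification resolved to *T. salvatum*, and
a junior homonym replaced by *T. meghalayense*). Two recently described
species from the Andaman Islands — *T. jarawa* (inglebyi group) and
*T. krishnani* (tonganum group) — are the only Indian species with published
worker type-series measurement ranges, and they anchor the package's
morphometric matching.

## What it computes

**Morphometric indices.** From 14 standard linear measurements (HL, HW, SL,
EL, PH, PW, WL, PSL, PTH, PTL, PTW, PPH, PPL, PPW; mm) the package derives
the 13 conventional ratio indices on the x100 scale, e.g.

    OI = EL/HW x 100    CI = HW/HL x 100    SI = SL/HW x 100
    DMI = PW/WL x 100   PSLI = PSL/HL x 100 ... PPI = PPW/PTW x 100

and applies the reporting convention of taxonomic descriptions (integers
for values ≥ 10 after rounding, one decimal below, half away from zero).

**Rounding-aware consistency checking.** Published measurements are
recorded to 3 decimals but printed at 2, so a printed index can differ from
its naive recomputation. With each printed measurement known only to
±h (default h = 0.005 mm), the feasible value of an index `num/den x 100`
is the interval attained at endpoint combinations; a printed index is
*consistent* when its own rounding band (±0.5 for integers, ±0.05 for
one-decimal values) intersects that interval. All 26 printed holotype
indices of the two new species pass this check, although 14 of them are not
reproducible by naive 2-decimal recomputation.

**Dichotomous keys as data.** The species-group key for India (12 couplets,
13 group terminals) and the species keys for the *T. inglebyi* and
*T. tonganum* groups (5 terminals each) ship as validated JSON. The engine
traverses them deterministically, flags couplets whose leads a specimen
satisfies both or neither of, and — under partial knowledge — returns
exactly the set of terminals reachable under some completion of the unknown
characters.

**Checklist analytics and matching.** The encoded checklist reproduces the
published totals; specimens are matched against the type-series ranges with
an in-range score per index family.

## Worked example

The *T. jarawa* holotype, as printed (2-decimal mm):

```r
library(tetrakey)
m <- measurement_set(HL = 0.56, HW = 0.52, SL = 0.32, EL = 0.05, PH = 0.27,
                     PW = 0.35, WL = 0.62, PSL = 0.10, PTL = 0.14, PTH = 0.17,
                     PTW = 0.16, PPL = 0.17, PPH = 0.18, PPW = 0.20,
                     recorded_decimals = 2)
round_index(compute_indices(m))[c("CI", "SI", "OI", "PSLI")]
#>   CI   SI   OI PSLI
#>   93   62   10   18
```

OI 10 and PSLI 18 equal the printed holotype values; CI 93 and SI 62 do not
(the description prints 94 and 60) — exactly the recording-vs-printing gap
the consistency checker accounts for:

```r
consistency_check(list(SI = "60", CI = "94"), m, h = 0.005)
#>   index printed band_lo band_hi feasible_lo feasible_hi    verdict
#> 1    SI      60    59.5    60.5    60.00000    63.10680 consistent
#> 2    CI      94    93.5    94.5    91.15044    94.59459 consistent
```

Both printed values are consistent: some 3-decimal measurement vector
printing as these 2-decimal values yields them.

Key traversal and measurement-based matching:

```r
kt <- load_key("tonganum_group")
traverse(kt, state_vector(kt, propodeal_armament = "unarmed"))
#> Key 'tonganum_group' -> krishnani
#>   [1A] Propodeum unarmed without teeth or spines

head(match_specimen(m), 3)
#>     species checkable     score n_checkable                            out_of_range
#> 1    jarawa      TRUE 1.0000000          13
#> 2 krishnani      TRUE 0.3076923          13 OI,SI,PSLI,LPeI,DPeI,PpNI,LPpI,DPpI,PPI
#> 3    barryi     FALSE        NA           0
```

The holotype scores 1.0 against its own species (all 13 indices inside the
h-widened feasible intervals of the published ranges); *T. krishnani*
conflicts on 9 index families; the remaining 40 species have no published
ranges and are reported `not_checkable`, not scored 0.

A command-line wrapper is installed at
`system.file("cli", "tetrakey", package = "tetrakey")` with subcommands
`measure`, `check`, `key validate`, `key run`, `match`, `summary`, `synth`
(see `?tk_cli`).

## Scope

Measurements are taken as given: no image-based measurement extraction, no
micro-CT reconstruction or 3D mesh handling, no nomenclatural resolution
against external authorities (the checklist is frozen), and no
probabilistic identification — partial-knowledge traversal is set-valued
only. See `vignettes/tetrakey-methods.Rmd` for the model, parameter and
design discussion.
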