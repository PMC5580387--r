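---
title: "Scoring, classifying and comparing cervico-thoracic transitional vertebrae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, classifying and comparing cervico-thoracic transitional vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvert)
```

## The scoring scheme

A mammalian seventh cervical vertebra (C7) normally bears no ribs; a first
thoracic (T1) bears the first true rib pair. A vertebra with rib
articulation facets but predominantly cervical morphology records a
partial homeotic cervical-to-thoracic transformation — a cervical rib.
`ctvert` encodes the 12 diagnostic characters (`a`–`l`) used to make this
call on isolated material: shape of the anterior and posterior centrum
faces (`a`, `b`, `d`), the ventral keel (`c`), vertebral-foramen
proportions (`e`), prezygapophyseal spacing and position (`f`, `g`),
postzygapophyseal orientation and spacing (`h`, `i`), the arch formed by
mammillary process, pedicle and transverse process (`j`), and rib facets
at the transverse process (`k`) and centrum (`l`). `character_definitions()`
returns the dictionary; the same table ships as
`extdata/character_definitions.csv`.

Each character is scored `C` (cervical), `X` (transitional), `T`
(thoracic) or `?` (missing). Five characters carry quantitative criteria,
implemented in `state_from_measurement()` as ratio thresholds:

| character | ratio | cervical band | thoracic band |
|---|---|---|---|
| `e` foramen shape | height/width | ≥ 0.75 | ≤ 0.73 |
| `d` anterior face depth | A–P length/centrum width | 0.40–0.50 | 0.25–0.35 |
| `f` prezygapophyseal spacing | gap/total width | ≈ 0.50 | ≈ 0.35 |
| `j` MPT arch | arch length/centrum height | ≥ 0.85 | ≤ 0.70 |
| `b` posterior end (juveniles) | height/width | ≥ 0.69 | < 0.64 |

### Gap zones and band edges

The printed bands are disjoint, leaving numeric gaps (e.g. 0.73–0.75 for
`e`). Ratios strictly inside a gap are scored `X`: transitional states
demonstrably occur in scored material, and the gaps are the only numeric
room for them. Band edges are applied exactly as worded — "75 % or more"
and "at least" are inclusive, "less than 64 %" is strict. For the two
characters with interval bands (`d`), values beyond both intervals on the
same side as a band take that band's state (an anterior face deeper than
50 % of centrum width is still cervical in form). Character `f` prints
only approximate point values (≈ 50 % vs ≈ 35 %), so its "bands" are
degenerate points and the rule reduces to: ≥ 0.50 cervical, ≤ 0.35
thoracic, in between transitional. These conventions are declared package
policy, not a documented practice of any particular scorer; the remaining
seven characters are qualitative and their states are data-entry inputs.
Character `b` has distinct adult (qualitative) and juvenile (quantitative)
criteria; with unknown age the adult criterion applies, with a warning.

### Bilateral characters and asymmetry

Characters `f`, `h`, `i`, `j`, `k`, `l` may be scored per side. For
counting, the specimen-level state is the more thoracic of the two sides
(`T` > `X` > `C`): a rib facet on one side only still evidences homeotic
change. Asymmetry itself — a hallmark of transitional vertebrae — is
captured separately by `asymmetry_flag()`: any informative left/right
state difference, differing recorded facet size classes, or an annotated
position asymmetry raises the flag. No quantitative threshold for
"conspicuous" asymmetry exists in the source material; any per-side
difference counts here.

## The classification rule

`classify()` applies a two-step rule. Rib facets are present when `k` or
`l` (either side) is non-cervical; absent when every preserved facet site
is cervical; indeterminate when both are missing. Then:

* facets absent → `C7`;
* facets present and `n_cervical + n_transitional ≥ 6` (of 12) → `CT`;
* facets present and the count cannot reach 6 even if every missing
  character were cervical → `T1`;
* otherwise → `INDETERMINATE`.

The threshold is absolute (6 of 12, i.e. at least 50 % cervical
morphology), not a fraction of the observed characters: with missing data
the rule abstains rather than extrapolates. The count-6 case is `CT`
("six or more"), which the regression matrix confirms: one published C/T
call has exactly six cervical-plus-transitional characters.
`INDETERMINATE` calls are excluded from every downstream denominator and
reported separately. One edge is package policy: with one facet character
observed cervical and the other missing, facets are scored absent —
absence is observable on the preserved element — while both-missing stays
indeterminate.

## Exact statistics

All inference is exact, as appropriate for samples of tens.

**Incidence.** `incidence(k, n)` reports `k/n` with the central
Clopper–Pearson interval at level 0.95 by default, computed from beta
quantiles (the closed form of inverting the binomial tails; the test
suite checks it against direct bisection on the binomial CDF). The
denominator is `#C7 + #CT`: T1s are not C7-region vertebrae.

**Fisher's exact test.** `fisher_exact()` conditions on both margins of
the 2×2 table; cell `a` is hypergeometric under the null.
`hypergeom_pmf()` evaluates the PMF in log space via `lchoose` for
stability. The one-sided p sums the tail in the observed direction
(relative to the conditional mean). The two-sided p uses the
minimum-likelihood rule — the sum of probabilities of all tables with
point probability at most the observed one (with a 1e−7 relative
tolerance on ties against floating-point jitter). This is the convention
of standard statistical software, and the only two-sided rule consistent
with the reference result for the table `[[5,27],[0,56]]`: minimum
likelihood gives p = 0.00514 (reported 0.005), whereas tail doubling
would give ≈ 0.010. Degenerate margins return p = 1 with a note rather
than an error.

**Odds ratio.** The unconditional cross-product ratio is undefined with
a zero cell; `odds_ratio()` instead returns the conditional
maximum-likelihood estimate under the noncentral hypergeometric model,
found by solving for the log odds at which the conditional expectation of
cell `a` equals its observed value, and diverging cleanly to `0` or `Inf`
when the observed count sits at the edge of its support.

**Reporting.** Proportions print as percent to one decimal, p-values to
three decimals, both rounded half-up at the printed digit; decimal
separator is always the dot.

## The synthetic-data model

`population_model()` + `generate_population()` produce seeded populations
with known ground truth so the pipeline can be property-tested and
calibrated without external data. Each specimen draws an archetype:

* **C7** — all 12 characters cervical;
* **CT** — facet characters forced non-cervical, and the total
  cervical-plus-transitional count drawn uniformly from 6–10, the range
  observed in published transitional vertebrae;
* **T1** — facets thoracic, cervical-plus-transitional count drawn 0–5.

Perturbations follow: per-character single-step state noise
(`C ↔ X ↔ T`, never a two-step jump — morphological gradation), directed
toward the opposite identity for the pure archetypes and in a random
direction for the mixed CT archetype; per-character missingness; and,
for CTs, per-side discordance on one eligible bilateral character at
`asymmetry_rate`. Injected discordance always makes one side one step
*more cervical* than the counting state, so it marks the record
asymmetric without altering its identity — which is what keeps the
noise-free recovery property exact.

Defaults state the world the scheme was built for, chosen once: CT
prevalence 0.15625 (the observed 5/32), no T1 contamination (the analyzed
fossil sample contains none), asymmetry rate 0.6 (3 of 5 transitional
vertebrae asymmetric), missing rate 0.1 (about 12.5 % of character cells
are unscorable on the characterized specimens, rounded once), and state
noise 0.02 (character scoring is reliable; small but nonzero). True
per-character state frequencies in any real population are unknowable
from published material; these are labelled conventions. The generator
does not emulate phylogenetic or temporal correlation between specimens,
collector bias, or size allometry — so a green simulation test
establishes the statistical machinery's calibration, not the realism of
any particular fossil assemblage.

`estimate_type1_error()` and `estimate_power()` run the *full* pipeline
(generate → classify → 2×2 table → exact test) per replicate, memoizing
p-values by table (a pure cache). Per-replicate seeds derive
deterministically from the top-level seed, so runs at different effect or
sample sizes are paired, sharpening monotonicity comparisons. One
convention worth noting: the significance *flag* on a test result uses
strict `p < α`, while the simulators count rejections at `p ≤ α` — the
standard level-α decision, and the only rule under which α = 1 rejects
with certainty (discrete data put positive mass on p = 1). At α = 0.05
the two coincide for all practical purposes. Calibration simulations use
noise-free, missingness-free models: the type-I error of the exact test
is a property of the sampling distribution of the counts, and
misclassification noise would conflate scoring error with test validity.

## Data and fixtures

The delimited-text schema (`read_specimen_table()` /
`write_specimen_table()`) is a plain CSV with one row per specimen, state
codes `C/X/T/?`, optional per-side and side-note columns, and optional
raw-measurement columns; round-trips are lossless and parse errors name
the offending line. Three fixtures ship in `extdata` with an MD5
manifest: the 32-specimen fossil inventory (full profiles where
published, all-cervical archetypes for specimens inventoried as normal
C7 — their inventory labels are kept as provenance metadata and never
consulted by the classifier), the 56 extant comparative C7s, and the
12-row fully characterized regression matrix. The extant inventory's
caption count (59) disagrees with its printed rows and the analysis text
(56); the fixture follows the printed rows. Three specimens share the
collection number "RGM cat a" across species and are disambiguated with a
species-epithet suffix to keep identifiers unique.

## Numerical choices and limitations

* Exact enumeration is used throughout; no chi-square or normal
  approximations, no mid-p variants, no stratified analysis.
* The conditional-MLE root search works on the log-odds scale with an
  adaptive bracket, tolerance 1e−10; the oracle in the tests maximizes
  the conditional likelihood directly.
* Monte-Carlo runs in the acceptance tests use 2000 replicates (scaled
  from larger exploratory runs to fit a single-CPU time budget; the
  resulting MC standard errors, ~0.011, are reported alongside every
  estimate).
* The classifier is deliberately non-probabilistic: a deterministic
  threshold rule with abstention. It will not distinguish a cervical rib
  from a rudimentary first rib; the conservative assumption that facets
  on a predominantly cervical vertebra are cervical ribs is inherited
  from the incidence argument it serves (cervicalized T1s are roughly two
  orders of magnitude rarer than cervical ribs).
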