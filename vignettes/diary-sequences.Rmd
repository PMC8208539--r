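---
title: "From episode diaries to weighted sequence summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From episode diaries to weighted sequence summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaryviz)
```

## The data model

A time-use diary records one respondent-day as contiguous activity
episodes covering the 24 hours that begin at 4:00 am. Minutes are
indexed 1..1440 from 4:00 am and episodes are half-open intervals
`[start_min, stop_min)`, so minute 1440 is the 3:59–4:00 am minute and a
complete day ends at stop minute 1441. Because respondents report until
the *end* of their last activity, raw diaries often run past 24 hours;
`cap_final_episode()` truncates the final activity at 3:59 am (dropping
any episode that starts after minute 1440) so every analyzed diary spans
exactly 1440 minutes. Capping only ever shortens: diaries covering fewer
than 1440 minutes are rejected rather than padded, since there is no
principled activity to pad with. `validate_diary()` applies the usual
diary quality checks — sequential episode order, no gaps or overlaps,
positive durations, a post-cap total of exactly 1440 minutes, and
resolvable activity codes — reporting all defects rather than failing on
the first.

## The eleven-category recode

Detailed activity lexicons run to 400+ six-digit codes; all summaries
here use eleven top-level categories in a fixed order: sleep, personal
care, housework, childcare, adult care, work, shopping, TV, eating,
leisure, travel. The recode is a longest-prefix crosswalk: a code
matches the entry whose pattern (2, 4 or 6 digits) is its longest
prefix, so a compact table covers the whole lexicon and deeper entries
override the tier they sit under (e.g. `0101` → sleep inside `01` →
personal care, `120303` → TV inside `12` → leisure). The bundled table
is a reconstruction of the conventional assignment — care of household
and non-household adults pooled as adult care, consumer purchases as
shopping, residual socializing/sports/religious/volunteer/education/
services/uncodeable time pooled with leisure, every travel code as
travel — and is deliberately replaceable through `load_crosswalk(path)`
for users whose codebook assigns differently (whether uncodeable time
belongs with leisure is a genuine judgment call; we pool it there).

## Sequences and the slot rule

`minute_sequence()` expands a capped diary to 1440 category-valued
minutes; `reduce_to_slots()` compresses those to 96 fifteen-minute
slots, slot *t* covering minutes `15(t−1)+1 .. 15t`. Taken literally, a
floor of `Minutes/15` over minutes 1..1440 yields 97 distinct indices
(0..96), which cannot label 96 slots; we therefore use
`slot(m) = ⌊(m−1)/15⌋ + 1`, which gives exactly 96 equal slots starting
at 4:00 am and matches the 4:00 am … 3:45 am axis labels of the
tempogram. A slot takes the category at its **first** minute — the
natural consequence of flooring episode start and end times to the
15-minute grid. Episodes that contain no slot-first minute (necessarily
shorter than 15 minutes) vanish at slot resolution; the absolute error
this induces in any time share is bounded by `100·(episodes×14)/1440`
percentage points, a bound the test suite asserts. A modal rule
(`rule = "modal"` in `reduce_to_slots()`, plurality within the slot,
earliest category breaking ties) is available for sensitivity checks;
the first-minute rule is the default because it is the one the floor
transformation implies.

## Weights, filters and the display subsample

Survey weights make the diary sample representative; every statistic
uses weights normalized over exactly the diaries being summarized,
`ŵ_j = w_j / Σ_k w_k`. Because each statistic re-normalizes within its
own subsample, any global rescaling of the weights cancels — so whether
the raw weights were calibrated to one multi-year sample or another
does not change any number this package produces. Subgroup filters
select on sex, weekday/weekend, marital status, parental status and
state before normalization. For display, `subsample_diaries()` draws a
seeded uniform sample without replacement of `min(800, N)` diaries —
uniform, not weight-proportional, because the weights already enter the
statistics and weighting the draw would count them twice. The seed is
an explicit argument (default 20210616) so every figure and table is
exactly reproducible; sampling restores the caller's RNG state.

## The four summaries

With `s_{j,t}` the category of diary *j* at slot *t* and `ŵ` the
normalized weights:

* **Percent of total time**: `100 · Σ_j ŵ_j #{t : s_{j,t}=i} / 96` per
  category; the eleven values partition the day and sum to 100.
* **Transitions**: every adjacent-slot change `s_{j,t−1}=u ≠ v=s_{j,t}`
  contributes `ŵ_j` to cell (u,v); continuations are ignored, giving
  the zero diagonal. The raw weighted counts are a weight-normalized
  transition mass; to present them as percentages we divide by the
  total off-diagonal mass and multiply by 100, so the matrix sums
  to 100. (Normalizing by the weight sum alone, which the count
  formula's prefactor suggests, does not yield proportions of
  transitions; the percent reading is the one the matrix display
  requires.) An input with no changes at all returns an all-zero
  matrix with a warning instead of an error, so batch runs survive
  degenerate subgroups.
* **Tempogram**: weighted occupancy of each category at each of the 96
  slots. In percent mode each slot sums to 100; in count mode the
  normalized weights are rescaled by the number of displayed diaries so
  cells read as "number of observations" out of the displayed sample.
* **State averages**: each state's diaries are treated as their own
  sample (weights re-normalized within the state); the weighted number
  of slots in each activity times 15 — the minutes a slot represents —
  gives average minutes per day, and the eleven averages sum to 1440.
  Diaries with an unknown state are excluded and counted.

## The synthetic generator

`simulate_diaries()` draws diaries from a semi-Markov profile: an
initial category at 4:00 am, spell durations geometric on the
15-minute grid (support 15, 30, 45, … minutes; `p = 15/mean`), and at
each spell end a new, different category from a row-stochastic,
zero-diagonal transition matrix, truncating the last spell at the
4:00 am boundary exactly as capping does. Geometric durations aligned
to the slot grid make the slot-level sequence first-order Markov, so
the change-conditional distribution of the next activity given a
change from *u* is exactly the profile row `P[u,·]` — which is what
makes transition recovery testable analytically: at n = 2000 diaries
the test suite requires every estimated conditional probability to lie
within three multinomial standard errors of the profile value.
Defaults emulate a plausible survey: everyone asleep at 4:00 am,
60-minute mean spells, half female, 2/7 weekend days, log-normal
weights (σ = 0.5); the recovery profile fixes the weights constant so
the multinomial error bound is exact. Episodes are emitted as detailed
six-digit codes (one representative per category) so the crosswalk
stage is exercised, never bypassed. The generator makes no attempt at
circadian time-inhomogeneity or realistic population marginals, so
passing tests certify the *computations*, not distributional realism of
any real survey.

## Numerical and interface choices

All arithmetic is double precision on integer slot counts, so the
worked-example statistics are exact; conservation identities are
asserted at 1e−9 (percent scales) and 1e−6 (minutes). Ties cannot occur
in the crosswalk (patterns are unique) nor in the modal slot rule
(earliest category wins). File ingest is a two-file rectangular layout
(episode file + person file joined on the diary id) described by a
remappable dialect whose defaults are the IPUMS ATUS-X variable names
(CASEID, ACTIVITY, START, DURATION, WT06, SEX, DAY, MARST, KIDUND18,
STATEFIP); start times may be integer offsets from 4:00 am or clock
strings, converted at ingest. Figures are base-graphics renderings and
every figure writes its underlying numeric table next to itself, so
downstream checks read data, never pixels; the state display is a
sorted table/bar chart rather than choropleth artwork. Test and
example problem sizes (≤ 2000 simulated diaries, 200 randomized oracle
cases, 10,000 subsample seeds on a 12-diary population) were chosen to
give tight Monte-Carlo bounds while keeping the whole suite around a
quarter of a minute.

## Limitations

Secondary/simultaneous activities, location and co-presence are out of
scope, as are design-based variance estimation, replicate weights, and
sequence-analysis distances or clustering. Sub-1440-minute diaries are
rejected, not imputed. The bundled crosswalk is a sensible
reconstruction, not an authoritative codebook; substantive analyses
should supply their own table.
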