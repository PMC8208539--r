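# diaryviz

Survey-weighted descriptive analysis of 24-hour time-use diaries.

Time-use surveys in the American Time Use Survey (ATUS) tradition record
one respondent-day as an ordered run of activity episodes — "slept from
4:00 am to 6:30 am, then showered, then commuted…" — together with a
person-level survey weight and demographic covariates. `diaryviz` is for
researchers who work with episode-level extracts of such data (e.g. IPUMS
ATUS-X exports) and want the standard descriptive toolkit: fixed-length
categorical day sequences, activity transition structure, time-of-day
rhythms, and state-level time budgets, all respecting the survey weights.

## What it computes

Each diary is validated (sequential, gap/overlap-free, 1440 minutes after
capping the final episode at 3:59 am), recoded from detailed 6-digit
activity codes to eleven top-level categories (sleep, personal care,
housework, childcare, adult care, work, shopping, TV, eating, leisure,
travel) via a longest-prefix crosswalk, and expanded to a 1440-minute
sequence that is reduced to 96 fifteen-minute slots, slot *t* taking the
category at its first minute, `slot(m) = ⌊(m−1)/15⌋ + 1`.

With normalized weights `ŵ_j = w_j / Σ_k w_k` over the selected diaries,
the four summaries are:

- **Percent of total time** per activity *i*:
  `100 · Σ_j ŵ_j · #{t : s_{j,t} = i} / 96`
- **Transition matrix**: weighted counts of changes `s_{j,t−1} = u ≠ v =
  s_{j,t}`, expressed as percent of all between-activity changes
  (11×11, zero diagonal, entries sum to 100)
- **Tempogram**: weighted count or percent of diaries in each activity at
  each of the 96 slots from 4:00 am to 3:45 am
- **State averages**: per US state, `15 · Σ_j ŵ_j · #{t : s_{j,t} = i}`
  average minutes per day (weights re-normalized within the state)

Subgroup filters (sex, weekday/weekend, marital status, parental status,
state) and a seeded 800-diary display subsample sit in front of every
summary. A seeded semi-Markov simulator generates fully synthetic
ATUS-like diaries so the entire pipeline runs without any data download.

## Worked example

```r
library(diaryviz)
xw <- load_crosswalk()                       # bundled 11-category recode

a <- new_diary("a", c("010101", "050101"),   # sleep 4am-4pm, work after
               start_min = c(1, 721), duration_min = c(720, 720),
               weight = 1)
b <- new_diary("b", "010101", 1, 1440, weight = 3)   # sleeps all day

ss <- build_sequence_set(list(a, b), xw)
percent_of_total_time(ss)
#> Percent of total time by activity:
#>         sleep personal_care     housework     childcare    adult_care
#>          87.5           0.0           0.0           0.0           0.0
#>          work      shopping            tv        eating       leisure
#>          12.5           0.0           0.0           0.0           0.0
#>        travel
#>           0.0
```

Diary `a` has normalized weight 0.25 and spends half its day asleep,
diary `b` has weight 0.75 and sleeps throughout, so sleep takes
`0.25·48/96 + 0.75·96/96 = 87.5%` of weighted time and work the
remaining 12.5%. A diary alternating sleep → work → sleep in three equal
blocks gives a transition matrix with 50% in each of the two off-diagonal
cells it visits, and a diary spending exactly one fifteen-minute slot on
adult care gives a state average of 15 minutes/day for that activity.

A shell interface with `validate`, `simulate`, `stats` and `plot`
subcommands wraps the same functions:

```sh
Rscript inst/cli/diaryviz.R simulate --n 800 --seed 1 \
    --out-episodes e.csv --out-persons p.csv
Rscript inst/cli/diaryviz.R stats --kind totals \
    --episodes e.csv --persons p.csv --out totals.csv
```

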