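---
title: "An agent-based model of cultural marginalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of cultural marginalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginsim)
```

## The model

`marginsim` implements an aspatial agent-based model of discrete cultural
trait transmission among four subcultures ("breeds") drawn from Merton's
strain-theory taxonomy: **conformists** (mainstream members with full
institutional access), **deviants** (marginalized members lacking the means
to achieve mainstream goals), **rebels** (members pursuing their own goals by
their own means) and **quiet mavericks** (inside-the-system innovators). The
model asks how two macro-level conditions shape marginalization —
operationalized as the population share of deviants — over 2.5 generations:

* **RTC (resistance to change)** sets a 4 x 4 matrix of probabilities that an
  agent adopts a trait from a partner of a given breed (rows = influencing
  source, columns = influenced adopter). Three calibrated panels (Low,
  Moderate, High) ship with the package. Two structural zeros hold at every
  level: a quiet maverick never adopts from another breed, and a rebel never
  adopts from a conformist.
* **Diversity** (a cultural tightness–looseness proxy) sets how many
  *secondary* traits individuate agents within a breed: 5 (Low), 7
  (Moderate) or 10 (High), alongside the 8 *primary* traits that define a
  breed's culture.

Traits are integers 0–50; primary trait values are initialized from a fixed
table in 0–21 and secondary traits are drawn per agent from 22–50. The
packaged defaults (initial counts 120/70/8/2 for
conformists/deviants/rebels/quiet mavericks in a population of 200, the RTC
panels, the initial trait table, ranges and lifespan) live in a YAML file —
`model_defaults()` — so every constant is overridable without code changes.

## The tick schedule

Each tick runs five phases, in order:

1. **Interaction.** Agents are visited once each in a fresh random order.
   A visited agent draws one trait value `v` uniformly from its list and
   seeks a partner uniformly among all other agents holding `v` (trait-based
   homophily; there is no spatial structure). If a partner exists, a uniform
   deviate is compared against the RTC cell for (partner breed -> agent
   breed); on success the agent overwrites one uniformly chosen slot of its
   own list with a trait of the partner. Updates apply immediately
   (asynchronous, ask-style scheduling). The initiator's interaction counter
   advances by exactly one whether or not a partner was found or adoption
   succeeded, so one generation (1,000 interactions) is exactly 1,000 ticks
   and the default 2,500-tick run spans 2.5 generations.
2. **Culture recompilation.** For each breed, all members' traits are pooled
   and the eight most frequent values become the breed's culture. A tie at
   the eighth rank is broken uniformly at random among the tied values. A
   breed with no members keeps its previous culture (so it can be
   repopulated); an under-full pool is padded from the previous culture.
3. **Breed switching.** Every agent is compared against all four fresh
   cultures and joins a breed whose culture it carries (see *List semantics*
   below); several qualifying breeds are resolved by a fair coin flip, none
   means the agent keeps its breed.
4. **Death and rebirth.** Agents at their lifespan (default 1,000
   interactions) are replaced in place: the offspring keeps the breed, draws
   `n ~ U{0..8}` traits uniformly without replacement from the parent's list
   into its first primary slots, and fills remaining primary/secondary slots
   from the respective value ranges. Because every agent's counter advances
   once per tick, rebirth is synchronized at ticks 1,000 and 2,000.
5. **Recording.** Fourteen dependent variables are recorded after the tick
   (and once at tick 0): four breed population proportions, four
   within-culture changes from the tick-0 cultures (`1 - overlap/8`), and six
   pairwise culture similarities (`overlap/8`).

A run summary is the arithmetic mean of each dependent variable over all
recorded ticks.

## List semantics — the central design choice

The source platform for models of this family stores an agent's traits as a
*list*, which can hold repeated values. Whether the trait collection behaves
as a multiset or as a set is consequential, and the package implements both
(`sim_config(list_semantics = ...)`):

* **`"multiset"` (default).** Adoption copies a uniformly chosen partner
  *slot*, so an agent can accumulate duplicate values; rebirth draws fresh
  values without exclusion; and breed switching asks whether more than seven
  of the agent's trait *occurrences* appear in a culture. Duplicates let
  lists concentrate on locally popular values, which speeds both
  within-breed convergence and cross-breed drift.
* **`"set"`.** Lists stay duplicate-free: adoption copies a trait the
  adopter lacks (a no-op when the partner offers nothing new), rebirth
  excludes already-held values, and switching requires a culture's full
  eight distinct values.

We made multiset semantics the default because it reproduces the qualitative
findings this model is known for at the standard 2,500-tick horizon: deviant
share increasing in RTC and decreasing in Diversity, conformist–deviant
similarity increasing in RTC and decreasing in Diversity, conformist
cultural change increasing in RTC, quiet-maverick share rising sharply with
Diversity, and rebels scarcest under high RTC. Under set semantics the model
converges toward the same qualitative attractor but roughly 3–4x more
slowly, so at 2,500 ticks the population-share orderings have not yet
emerged; we verified this with long-horizon (10,000-tick) runs. Set
semantics remains available as the cleaner normalization for studying the
mechanism itself.

Neither semantics reproduces every published headline number, and we did not
tune toward them: under the multiset default the breed shares mix more
evenly at equilibrium (conformists fall further, rebels and quiet mavericks
rise higher) than the reported means, while the deviant share and the
change/similarity orderings track closely. The residual gap is consistent
with an unstated scheduling or bookkeeping detail of the original
implementation, which is not publicly retrievable; the package documents the
two defensible readings rather than interpolating between them.

## Randomness and reproducibility

One master seed per run (in `sim_config()`) seeds R's global stream; every
stochastic step consumes it through a single primitive (`floor(u * n)`) in a
documented fixed order — initialization, then per tick: agent shuffle,
interaction draws, culture tie-breaks, switching coin flips, rebirth draws.
The production engine is compiled (Rcpp) and consumes R's `unif_rand()`
stream with the identical mapping, so `run_single(cfg, engine = "cpp")` and
`engine = "r"` (a literal pure-R enumeration of the schedule, kept as an
independent oracle) are bit-identical; the test suite asserts this across
conditions, seeds and both semantics. Design seeds are derived
deterministically from `(base_seed, cell, replicate)` and are distinct
within any design with fewer than 126 replicates per cell.

## Experiment and statistics

`run_design()` executes the RTC(3) x Diversity(3) factorial (default 25
replicates per cell, 225 runs; the package's desk-scale analyses use 10
replicates per cell, 90 runs, which keeps a full factorial under ~3 minutes
on one CPU while estimating marginal means to about +/-0.01).
`analyze_design()` fits a fixed-effects two-way ANOVA with interaction
(`stats::aov`) to each of eleven dependent variables (four proportions, four
changes, three similarities to the conformist culture). Effect sizes are
classical eta-squared (`SS_effect / SS_total`, not partial), so the three
effects' values sum to at most one; degrees of freedom in the 3 x 3 design
with `r` replicates are 2, 2, 4 and 9(r-1). Post-hoc pairwise comparisons
use Tukey's HSD at alpha = 0.05 — the standard all-pairs procedure for a
balanced factorial; no other adjustment is implied by the model. The test
suite checks the decomposition against hand-computed sums of squares and the
Tukey p-values against the studentized-range formula.

## Numerical and degenerate-case choices

* Culture ties consume randomness only when the tie class at the eighth rank
  is strictly larger than the number of places to fill; an exact fit is
  deterministic.
* A breed with no members keeps its last culture, so extinct breeds can be
  re-entered; an under-full trait pool (possible only near extinction) is
  padded from the previous culture, highest pooled frequency first.
* The initial trait table contains one value (22) that also begins the
  secondary range; initialization draws secondary traits without replacement
  excluding any value already held, so initial lists are duplicate-free
  under both semantics.
* `rtc_matrix()` validates the unit diagonal and the two structural zeros;
  experiments that need fully frozen dynamics can zero the matrix on the
  config object directly (the tests do this to verify the no-adoption
  limit).

## What the simulations do and do not show

All experiments are self-generated: the model is the data generator, run at
the published conditions (200 agents, 120/70/8/2, lifespan 1,000, 2,500
ticks, the three RTC panels, 5/7/10 secondary traits). Passing tests
demonstrate internal correctness (schedule fidelity, conservation,
determinism, statistical layer) and reproduction of the qualitative
condition effects under the default semantics. They do not validate the
model against empirical social data, and the headline *magnitudes* of breed
shares are sensitive to the list-semantics reading, as discussed above — a
caution that applies equally to substantive interpretation of the original
results.

## Known limitations

* No spatial or network structure; partner choice is global and trait-based.
* All breeds share one Diversity level within a run.
* The 14 dependent variables are culture-level (the 8-trait cultures), not
  agent-level averages; an agent-pair similarity variant would be a
  reasonable sensitivity analysis but is not implemented.
* Replicates are run serially; the derived per-run seeds make external
  parallelization safe (byte-identical summaries), but the package does not
  schedule jobs itself.
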