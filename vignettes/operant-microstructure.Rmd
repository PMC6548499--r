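---
title: "Microstructure of reward seeking and retrieval: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructure of reward seeking and retrieval: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(operantmicro)
```

## The behavioral problem

In self-paced operant tasks, a hungry rat presses a lever that occasionally
delivers a food pellet into a recessed cup. Two distinguishable responses
make up performance: *reward seeking* (the lever press) and *reward
retrieval* (a food-cup approach, recorded as a photobeam break at the cup
entrance). When reinforcement is sparse, rats do not check the cup after
every press. Instead they alternate between two strategies: a
*press-approach action chunk*, in which the press is immediately followed by
a retrieval attempt, and a *discrete press* with no retrieval. The fraction
of presses followed by an approach — and how that fraction moves under
reward-paired cues (Pavlovian-to-instrumental transfer, PIT) and
outcome devaluation — is the scientific quantity this package computes.

The package provides four layers:

1. **events_io** — a canonical tidy event-log format (CSV) and its
   validation;
2. **microstructure** — press classification, approach-episode detection and
   peri-event approach-probability histograms;
3. **assays / stats** — CS-period tables, PIT scores, devaluation tables,
   conditioning scores, t tests, correlation and a Poisson mixed-model
   contract for counts;
4. **simulator** — a generative virtual rat that produces event logs with
   the statistical structure the analysis assumes, so every stage can be
   tested by parameter recovery at desk scale.

## The classification model

A food-cup entry at time $t$ is *press-contingent* when the most recent
press $p$ satisfies $t - p \in (0, c]$ with cutoff $c = 2.5$ s, the
conventional bound on the sharp post-press retrieval peak. Three details are
fixed by convention, because the verbal rule underdetermines them:

* **Half-open intervals.** "Within $c$ seconds after" always means
  $(0, c]$. A press exactly at a CS onset belongs to the CS period
  ($(\mathrm{onset}, \mathrm{offset}]$); the matching baseline is the 120 s
  window $(\mathrm{onset} - 120, \mathrm{onset}]$.
* **Most-recent attribution.** An entry is never credited to an earlier
  press across an intervening press: the approach completes the press
  immediately preceding it. Consequently the presses partition exactly into
  `with_approach` and `without_approach`.
* **Entries are onsets.** A press during ongoing cup occupancy has no new
  entry to attribute and is classified `without_approach`; `foodcup_exit`
  events are retained for bout duration but ignored by classification.

A press is *reinforced* when a pellet delivery or dispenser cue is logged at
the press time; simultaneous events are ordered by a fixed tie rank
(press < pellet < dispenser cue < entry < exit) so this test is
deterministic. In cues-only tests (dispenser activated, pellet diverted to
an external cup) the dispenser cue alone defines reinforcement, which is
what makes the feedback conditions comparable.

Entries that are not press-contingent are grouped into approach episodes:
an entry within 2.5 s of the previous entry continues that entry's episode,
anything else starts a new one. Episodes whose first entry is
press-contingent are contingent retrieval episodes; the rest are
*noncontingent bouts*, which by construction begin more than 2.5 s after
the most recent press or approach. Chaining an entry onto the previous
entry's episode (rather than forcing it to stand alone) is our convention;
it makes the conservation identity exact: press-contingent episode entries
plus noncontingent bout entries equal total entries. Both the classifier
and the episode detector are checked in the test suite against exhaustive
brute-force implementations that examine every (press, entry) pair, on a
thousand random logs up to 10,000 events.

The peri-event histogram (`peri_event_probability()`) reports, for each
0.5 s bin in a ($-5$, $+10$] s window around an alignment event, the
fraction of alignment events with at least one entry onset in that bin.
The defaults resolve the 2.5 s contingency structure while keeping per-bin
counts stable in a 30-min session; both are parameters. An empty alignment
set raises an error rather than returning zero, because "no reinforced
presses" and "never approaches after reinforced presses" are different
findings. The same principle applies to proportions: a period with no
presses yields `NA`, which is excluded from proportion analyses rather than
imputed as zero.

## Derived assay measures

For PIT test sessions (8 min lead-in extinction, then four CS+ and four
CS− trials of 120 s with a 180 s fixed ITI), `period_response_table()`
counts presses, chunks and bout starts per cue type and period, summed over
the four trials of each type. The **PIT score** is total CS+ presses minus
total pre-CS+ presses — totals, not per-trial means — optionally restricted
to presses with or without approach; the restriction is additive by
construction. When a design includes duplicate tests per drug condition,
per-subject scores are averaged within drug before group statistics, the
conventional reduction to one value per subject per condition.

For devaluation tests (5 min nonreinforced phase followed by 15 min
reinforced), `devaluation_table()` computes press counts and
proportion-with-approach per lever value from the nonreinforced phase only,
window $(0, 300]$ s. Pavlovian conditioning is scored per trial as the
entry rate from CS onset to the first pellet delivery (excluding
delivery-evoked responding; the full cue window if no pellet fell) against
the rate in the 120 s pre-CS baseline.

## The statistical layer

Count measures are modeled with a Poisson response and log link;
fixed effects are the full factorial of the design factors and the random
structure is by-subject uncorrelated intercepts adjusted for the named
within-subject factors, implemented as `(1 | subject)` plus one
`(1 | subject:factor)` term per named factor. The numerical fit is
delegated to `lme4` (Laplace approximation, default optimizer, fixed
settings); with no random factors the model reduces to an IRLS GLM, which
the test suite exploits as an oracle. Coefficients are reported
unstandardized on the link scale. Factor and interaction tests come from
`car::Anova` type II — likelihood-ratio chi-square for GLMs, Wald
chi-square for mixed models, F for Gaussian fits. We fit with R's default
treatment contrasts (so the degenerate two-group Poisson example has the
closed-form solution intercept $\log 3$, slope $\log 8/3$); type III tests
under treatment contrasts would be misleading, and nothing in the analysis
contract requires them. A boundary (singular) fit — random-effect variance
estimated at zero — is reported as converged, because it is a legitimate
maximum of the likelihood; genuine optimizer failures set
`converged = FALSE` and carry the messages.

Proportion measures are square-root transformed (`sqrt_prop()`) before
analysis to correct positive skew and analyzed with the Gaussian family;
whether simple contrasts are run on transformed or raw proportions is a
user flag in the sense that both `sqrt_prop(x)` and `x` can be passed to
`paired_t()` — the pipeline uses transformed values. All t tests are
two-sided at $\alpha = .05$, and no multiple-testing correction is applied.
Degenerate zero-variance differences return $t = 0$ (no effect) or signed
infinity rather than `NaN`.

## The generative virtual rat

`sim_config()` fixes the generative parameters; sessions are produced by a
discrete-time scan at `time_step_s` (default 0.1 s, small enough that the
per-step hazard $r\,\Delta t$ approximation is accurate at the rates
involved). The defaults describe a well-trained rat under sparse
reinforcement:

| parameter | default | meaning |
|---|---|---|
| `press_rate_per_min` | 5 | baseline press hazard (well-trained RI-60 performance) |
| `p_approach_feedback` | 0.9 | P(approach) after a press with dispenser feedback |
| `p_chunk_nonreinforced` | 0.1 | P(approach) after a nonreinforced, uncued press |
| `approach_latency_mean_s` / `_max_s` | 0.4 / 2.5 | truncated-exponential press-to-entry latency |
| `background_approach_rate_per_min` | 0.5 | spontaneous entry rate |
| `cs_press_multiplier` | 3 | CS+ effect on press hazard |
| `cs_chunk_multiplier` | 3 | CS+ effect on chunk probability (capped at 1) |
| `cs_entry_multiplier` | 3 | CS+ effect on background entry rate |
| `deval_press_multiplier_discrete` / `_chunk` | 0.2 / 0.8 | devaluation suppression by press type |

Base rates for this preparation are not reported numerically anywhere we
could calibrate to, so the defaults are chosen once for qualitative
realism: near-certain retrieval after feedback versus sporadic checking
otherwise; a roughly threefold cue-evoked press increase; chunks largely
spared by devaluation while discrete presses are strongly suppressed. With
these defaults the devalued lever's expected proportion-with-approach
follows from mixture algebra,
$p\,m_c / (p\,m_c + (1-p)\,m_d) = 0.08/0.26 \approx 0.31$ against $0.10$ on
the valued lever, reproducing the signature *increase* in retrieval
probability on the devalued lever even as total devalued pressing falls.

Design choices worth stating explicitly:

* **Independent processes.** Presses, contingent approaches and background
  entries are conditionally independent streams: no motor refractory
  period is modeled. This keeps closed-form expectations exact (e.g. the
  expected PIT score under a CS+ press multiplier $m$ is
  $(m-1)\,r \cdot 8$ min), at the cost that an occasional press lands
  between a press and its approach and steals the attribution. The default
  latency mean of 0.4 s keeps this attribution slip rare at realistic
  press rates (about 3% of presses at 5/min) while matching a sharp,
  sub-second retrieval peak; parameter-recovery tests bound the resulting
  bias within the ±0.05 acceptance band.
* **Schedules.** RI arming delays are exponential with the nominal mean
  (constant-hazard RI, the canonical implementation; a degenerate
  constant-interval option exists for deterministic tests), and the timer
  resets on reinforcer delivery. RR reinforces each press with probability
  $1/\mathrm{ratio}$; CRF is RR-1. Random-time pellet delivery during the
  CS+ is a Poisson process at rate $1/30\,\mathrm{s}^{-1}$, giving the
  scripted 4 pellets per 2-min trial in expectation.
* **Session termination.** Sessions end at 30 min or at the reward cap
  (20); a capped session ends 5 s after the final delivery so that the
  terminal retrieval is recorded. Ending at the exact delivery instant
  would censor exactly one reinforced approach per capped session and
  bias recovered retrieval probabilities downward by about 1/cap.
* **Trial scripts.** PIT trial order is a seeded permutation with at most
  two consecutive same-type trials; Pavlovian inter-trial spacing is drawn
  uniformly on the stated 4–6 min onset-to-onset range. Devaluation acts
  multiplicatively on the press-initiation hazard, separately for intended
  chunk and discrete presses, during the nonreinforced phase.
* **Hardware realism.** Entry times are debounced at 50 ms and every entry
  receives an exit strictly before the next entry, so generated logs
  always satisfy the entry/exit alternation invariant. All event times are
  stored at millisecond resolution, which is what makes the CSV
  round-trip byte-exact.
* **Reproducibility.** One root seed; each (subject, session) gets a
  derived substream, so cohorts are bitwise reproducible and subjects are
  independent.

What the simulator does *not* emulate: learning dynamics (acquisition or
extinction curves within or across sessions), within-session satiety,
post-reinforcement pausing or any other serial dependence in pressing,
multi-entry retrieval bouts locked to pellet consumption time, and any
pharmacological mechanism — drug or group effects enter only as user-set
multipliers on the generative parameters. Tests that pass on simulated
cohorts therefore validate the *pipeline arithmetic* under the model's
assumptions, not the model's fidelity to any particular real cohort.

## Numerical and degenerate-input conventions

Times are rounded to 1 ms on log construction; equality tests on event
times are exact at that resolution (feedback attribution uses the stored
values, with a $10^{-6}$ s guard where strict inequalities meet floating
point). Undefined proportions propagate as `NA` and are excluded, never
imputed. Ties between simultaneous events are resolved by the fixed event
rank. `pit_score()` refuses tables spanning more than one session;
`peri_event_probability()` refuses empty alignment sets; schedule
constructors reject non-positive parameters at construction so the step
function never sees a degenerate state.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in about a minute: oracle equivalence on 1,000 random logs
(five of them at 2,000–10,000 events); parameter recovery with 20 subjects
× 6 RI-60s sessions; PIT calibration with 200 simulated subjects per
condition; t-test calibration with 10,000 null replicates. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
(e.g. binomial SE ≈ 0.002 at 10,000 replicates against a ±0.008 band).

## Known limitations

* The classification cutoff is a parameter, not an estimate; no automatic
  cutoff selection from the peri-event histogram is attempted.
* Whether repeated beam interruptions during continuous occupancy should
  be debounced in *real* data is an acquisition-system question; the
  validator enforces strict entry/exit alternation, so upstream converters
  must resolve it.
* The reinforced phase of devaluation tests is summarized by raw counts
  only; no consumption or satiety modeling.
* Proprietary operant-chamber raw formats are out of scope; the package
  consumes only the tidy CSV schema.

## A compact worked example

```{r example}
cfg <- sim_config(seed = 11)
log <- simulate_instrumental_session(cfg, schedule_spec("RI", 60))
cp <- classify_presses(log)
c(reinforced = as.numeric(proportion_with_approach(cp, cp$reinforced)),
  nonreinforced = as.numeric(proportion_with_approach(cp, !cp$reinforced)))
```

The recovered proportions estimate the generative
`p_approach_feedback = 0.9` and `p_chunk_nonreinforced = 0.1` (the
nonreinforced estimate sits slightly above 0.1 because background entries
occasionally land inside a press's contingency window).
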