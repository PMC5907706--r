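---
title: "A hospital budget impact model for intracameral versus topical mydriasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hospital budget impact model for intracameral versus topical mydriasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mydriabim)
```

## The decision problem

During phacoemulsification cataract surgery the pupil must stay dilated for
the whole operation. Two strategies are compared from the hospital's
perspective over a one-year horizon:

* **Reference (eye drops):** nurses instil topical tropicamide and
  phenylephrine in repeated pre-operative sessions; patients wait for
  dilation before surgery.
* **Intervention (intracameral injection):** the surgeon injects a combined
  mydriatic/anaesthetic solution at the start of surgery; no instillation
  sessions and a much shorter wait.

Either way, mydriasis can still fail intra-operatively, at different rates
per arm; a failure costs extra intra-operative time, surgeon time between
operations, and a mix of rescue treatments (adrenaline, additional drops,
mechanical iris tools, cyclopentolate).

The model is a deterministic cohort decision tree: for a hospital performing
`n_patients` operations a year it computes annual *expectations* of resource
use and cost in each arm, their incremental difference, and the throughput
value of freed surgeon time. There is no time dependence, queueing or
scheduling dynamics — only annual expected values — and no adverse-event,
anaesthesia, post-operative medication or room-cost components, which carry
no differential inputs in this setting.

## Inputs and their defaults

The packaged base case (`base_case()`, also shipped as
`inst/extdata/basecase_table1.yaml`) describes a UK hospital performing
3,000 operations a year, with all money in GBP:

```{r}
tidy(base_case())
```

Key defaults and their rationale:

* **Failure probabilities** 1.1% (intervention) vs 5.3% (reference), with
  sensitivity bounds from trial confidence intervals.
* **Waiting time** 8.70 vs 37.90 min/patient; **instillation workload**
  3 sessions of 3 min each in the reference arm, none in the intervention
  arm.
* **Per-operation surgeon time and theatre occupancy** are stored at full
  precision as 12.025 and 11.335 min. These are back-derived from the annual
  totals they must reproduce (601.25 h and 566.75 h over 3,000 operations);
  their conventional two-decimal renderings are 12.03 and 11.34. Storing the
  rounded values instead would propagate a systematic error of up to 0.3 h
  into every annual aggregate.
* **Failure time costs:** 10 min extra intra-operative time plus 10 min lost
  between operations, per failure, in both arms.
* **Staff rates** 43.12 (nurse) and 147.26 (surgeon) GBP/h.
* **Drug prices:** 6.00 for the injectable; 0.54 + 0.57 for the two drops,
  one vial of each per patient (`patients_per_vial = 1`).
* **Rescue mixture:** marginal use frequencies per failure
  (4%, 93%, 14%, 4%, 32%, 0%) times unit costs, giving an expected
  3.2549 GBP per failure. The frequencies may sum to more than one — several
  rescue treatments can be used on one patient — so they are applied
  independently and never renormalised. The zero-frequency "others"
  component is stored explicitly so the mixture is closed under its
  published labels.
* **`revenue_per_operation` = 744.70** is *not* a published input. It is
  back-derived so that the throughput module's revenue scale is plausible,
  and it only ever enters linearly; analyses that need revenue should set
  their own tariff.

Every scalar is addressable by a dotted path
(`set_parameter(config, "reference.session_duration_min", 5)`), scenario
files may omit any field (defaults fill in), and serialisation round-trips
exactly.

## Accounting choices

Two bookkeeping rules are genuine modelling decisions rather than
arithmetic:

* **Theatre occupancy includes both failure delay components.** Annual
  theatre hours are `n * or_occupancy_min / 60` plus the failure delay
  (intra-operative extra time *and* between-operation loss). This is the
  only accounting under which theatre time equals total surgeon time in both
  arms (612.25 and 619.75 h), which the base case requires. Whether the
  between-operation loss truly occupies the theatre is not observable from
  the inputs; the model adopts the consistent reading. Per-operation theatre
  occupancy is nevertheless kept as a parameter separate from surgeon
  working time, even though the two coincide numerically in the base case.
* **Surgeon "in-operation" time uses `surgeon_working_time_min` only**; the
  failure delay is carried in its own field, and their sum is what staff
  costs are charged on.

Expected failures (33 and 159 in the base case) are carried unrounded
through all downstream computation; rounding to whole pounds, pence and
two-decimal hours happens only in rendered views (`print`, CSV outputs).
Differences are computed at full precision *then* rounded, so the rendered
saving (−6,249) can differ by a few pounds from subtracting the rendered
totals.

## Throughput benefit

Saved surgeon minutes are
`-(total surgeon hours difference) * 60` (450 in the base case). The number
of additional operations divides this by the time one more operation would
actually take under the intervention: its expected per-operation surgeon
time `t_s + p (t_e + t_b)` = 12.245 min, giving 36.75 operations. Dividing
instead by the no-failure time 12.025 would give 37.42; the expected-time
divisor is the defensible reading of "time needed for a cataract surgery"
and is the package's choice.

The expected net benefit has no canonical formula at all, so it is an
explicit function argument. The default,
`additional_revenue - operations_gained * intervention cost_per_patient`,
charges each extra operation its own modelled mydriasis cost. With the
back-derived revenue constant it yields about 26,041 GBP/year on the base
case. Users with a real tariff and marginal-cost estimate should supply
their own rule; the packaged numbers for revenue and net benefit are scale
illustrations, not reproducible facts.

## One-way sensitivity analysis

`one_way_dsa()` takes each bound entry, rebuilds the *entire* model at the
low and at the high value with everything else at base, and records the
incremental total cost — the quantity whose zero crossing means "no economic
impact". Entries are sorted by descending span with lexicographic
tie-breaking on the parameter path, so the output (and the CSV the CLI
writes) is byte-stable.

Three structural choices:

* **Bounds are applied verbatim**, including internally odd ones (the
  failure extra time has high bound 7.5 below its base 10; the adrenaline
  use frequency has low bound 39% above its base 4%). The engine evaluates
  whatever interval it is given; repairing intervals would silently change
  the analysis.
* **One published price = one tornado bar.** The tropicamide and
  phenylephrine prices feed both the reference arm's acquisition cost and
  the rescue mixture, so their entries carry both dotted paths and set them
  together.
* **The rescue mixture's alternative profiles are swapped wholesale** (all
  component frequencies together), because the published low/high profiles are
  not per-component intervals. The tornado entry reports the expected
  rescue cost per failure (3.2549 base, 5.1010 low) as its scalar summary.

On the base case the tornado is led, in order of span, by the session
duration (22,638), the intervention drug price (18,000), the session count
(12,936) and the nurse rate (10,886). The incremental cost changes sign at
the session-duration low bound (+3,453) and the drug-price high bound
(+2,751) — and, by a hairline, at the low session count: two sessions
instead of three remove one third of the reference arm's nurse cost and
leave the incremental at +219, about 1.7% of that entry's span. On a tornado
diagram this third crossing is invisible, but the model reports it honestly;
`sign_flip` is defined strictly as the low/high incrementals straddling
zero.

Parameters that no arm's costs depend on (waiting time, theatre occupancy —
there being no room costs) produce spans of exactly zero, which doubles as a
structural regression check.

## The microsimulation oracle

`simulate_cohort()` is the package's synthetic-data generator and the
brute-force check on every deterministic expectation. Per patient it draws
the failure flag Bernoulli(`p_failure`); given failure, each rescue
component is used independently with its marginal frequency, and the
failure's fixed time penalties accrue. Patient times are otherwise
deterministic: no variances are modelled because none are published, so
independence of rescue draws is the minimal assumption consistent with the
expected-cost formula. Aggregating a replicate of `n_patients` per arm
reproduces, field for field, the cohort engine's quantities; the cohort
model is exactly the expectation of this generative process.

`oracle_check()` therefore requires deterministic fields (waiting, nurse
hours and cost, in-operation surgeon hours, drug cost) to match exactly, and
every stochastic field to sit within three standard errors of the Monte
Carlo mean. Comparisons are refused across different scenarios (a
fingerprint hash travels with the summary). Seeding is scoped: the caller's
random state is saved and restored, so no global state leaks.

The validation in the test suite uses 200 replicates of 3,000 patients per
arm (and smaller runs of 40–50 replicates for targeted checks); the
structural property tests draw 1,000 randomized valid configurations. These
sizes give three-standard-error bands of a fraction of a percent on the
base-case totals while keeping the default test run fast. Note what passing
does and does not show: it certifies the internal consistency of the
deterministic and stochastic implementations under the model's own
assumptions, not that real theatre lists behave like independent Bernoulli
draws — real data have inter-patient correlation, scheduling constraints and
time variability the generator deliberately omits.

## Numerical and degenerate-input behaviour

* All arithmetic is double precision; the additivity identities
  (`work + treatment = total`, etc.) are construction-exact.
* `n_patients = 0` is legal and yields all-zero summaries (with
  `cost_per_patient` defined as 0); a zero expected per-operation surgeon
  time makes `operations_gained` undefined and raises a configuration error
  rather than dividing by zero.
* A single-replicate microsimulation has undefined standard errors; they are
  reported as `NA` and the oracle treats the band as unbounded, so the
  verdict stays well-defined.
* Validation errors carry typed classes (`bim_validation_error`,
  `bim_range_error`, `bim_lookup_error`, `bim_hash_error`,
  `bim_config_error`) naming the offending field; the CLI maps them to
  distinct exit codes.

## Known limitations

* Annual expectations only: no queueing, session-level scheduling, surgeon
  learning, or capacity constraints.
* The hospital perspective excludes patient and carer time, adverse events,
  anaesthesia, post-operative medication and room costs.
* Revenue and net benefit depend on a non-published constant and a chosen
  rule (above); treat them as scale illustrations unless configured with
  local values.
* Sensitivity bounds are taken as given; where an interval does not bracket
  its base value the tornado bar is one-sided by construction.
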