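---
title: "Enhancing death reporting from linked administrative records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing death reporting from linked administrative records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkenhance)
```

## The problem

Death registrations under-report membership of some population groups —
notably Aboriginal and Torres Strait Islander peoples in Australian
registration data — which biases every mortality indicator computed from
them. When each death record is linked to the person's administrative
health records (hospital admissions, emergency department attendances,
perinatal and birth registration records), each linked record carries its
own independently collected report of the person's status. `linkenhance`
implements the standard enhancement approach built on that evidence, plus
the machinery needed to evaluate it: mortality indicators, a
misclassification sensitivity analysis, and a synthetic linked-data
generator, since real linked registry extracts are confidential.

## Units of information

Raw linked records are not independent evidence: a hospital admission that
continues through a transfer generates several episode rows whose status
fields were typically copied once at admission. The package therefore
derives *units of information*:

* each emergency department attendance, perinatal record and birth
  registration record is one unit;
* admitted-patient episodes are collapsed into hospital *stays* — episodes
  are merged when the next admission falls on (or within `gap_days` of)
  the running discharge date, or when an explicit transfer pointer links
  the two episodes. One stay is one unit.

Within a stay, *any yes wins*: the stay reports membership if any
constituent episode does; it reports "no" if at least one non-missing flag
is no and none is yes; it is missing only when every flag is missing. The
rationale is that the stay represents a single encounter's report, and an
affirmative report anywhere during the encounter is that report.

On infant birth records the parent's report stands in for the infant's:
a perinatal record reports the infant as a member whenever the mother is
so recorded; a birth registration, whenever the mother or father is.

Two conventions are configurable because the convention itself is a
methodological choice rather than a fact:

* units whose flag is missing are excluded from the algorithm's unit
  counts by default (`count_missing_units = FALSE`) — a missing field
  carries no information;
* the death registration itself is never emitted as a unit. The
  weight-of-evidence thresholds below apply only to deaths *not* already
  reported, for which the death record contributes no affirmative
  evidence; counting it would double-count the baseline.

## The three reporting methods

With $n$ countable units of which $k$ report membership:

* **as reported** — the death registration flag alone ("yes" only;
  a missing flag is not a report, but such deaths remain eligible for
  enhancement);
* **at least one report** — enhanced if any unit reports membership;
* **weight-of-evidence algorithm** — enhanced if $n \ge 3$ and $k \ge 2$,
  or $1 \le n \le 2$ and $k \ge 1$;
* a **proportion-threshold** family ($k/n \ge t$ for $t \in \{0.5, 0.75,
  0.9, \dots\}$) is provided for comparison; it demands strictly more
  evidence than the count-based algorithm.

Every method accepts an already-reported death as reported, so the counts
are always ordered: as reported $\le$ algorithm $\le$ at least one.

## Mortality indicators

`build_tables()` produces the three standard report tables: stratified
counts with percent increases (rounded to one decimal, half away from
zero, matching how published tables round), median age at death per
stratum and method, and indirectly standardised mortality ratios.

For the SMR, standard rates by sex and five-year age band are applied to
the study population and summed to an expected count $E$; the SMR is
$100\,d/E$ for $d$ observed deaths. Exact limits use the Poisson–gamma
relationship:

$$\mathrm{CI} = \left[\frac{100\,G^{-1}_{d}(\alpha/2)}{E},\;
\frac{100\,G^{-1}_{d+1}(1-\alpha/2)}{E}\right],$$

where $G^{-1}_{s}$ is the quantile of a unit-scale gamma with shape $s$,
and the lower limit is 0 when $d = 0$. These are equivalently half the
$\chi^2$ quantiles at $2d$ and $2(d+1)$ degrees of freedom — the test
suite checks both routes agree to $10^{-9}$. The interval is exact and
therefore conservative for small counts; simulated coverage of the 95%
interval is required to be at least 93%.

Cause-specific SMRs need cause-specific standard rates: the rates table
accepts an optional `cause` column for that purpose. Supplied with
all-cause rates only, the table reports all-cause SMRs alone rather than
silently mis-standardising.

## Misclassification sensitivity

A record that falsely reports a non-member as a member can, under
"at least one report", flip a whole death. Each false record flips at
most one death, so an excess of $\Delta$ deaths across $N$ linked records
implies a per-record false-report rate of at least $10^4\,\Delta/N$ per
10,000 records — `required_misclassification_rate(128, 648746)` gives
1.97, which is the arithmetic behind quoting such excesses as requiring
only "about 2 per 10,000". The exact denominator behind the published
approximation is not recoverable; the package implements the transparent
definition (excess over all linked records) and reports two decimals.

`expected_spurious_enhancements()` gives the closed-form expectation of
spurious enhancements under independent per-unit false positives
(binomial tails per death), and `sensitivity_sweep()` pushes a grid of
false-positive rates through the full generator-plus-enhancement
pipeline. The sweep applies the rate to the linked-record sources only,
leaving the death record at its configured value, so the baseline stays
fixed and the methods' differential fragility is isolated. Dependent
errors (a wrong flag copied across a person's records) are out of scope
and would make the algorithm less protective than the independent model
suggests.

## The synthetic world

`generate_cohort()` draws a cohort in which enhancement is the *truth
recovery* problem the method faces in production:

* each death has a latent true status (prevalence 0.02 by default —
  roughly the group's share of deaths in the motivating setting);
* each record source reports a true member with its own sensitivity:
  death registration 0.76, admitted-patient 0.88, perinatal 0.68 —
  external validation figures for the motivating datasets — and 0.80 for
  ED and birth registration, which have no published validation and are
  explicitly placeholders;
* non-members' records flag yes with a per-source false-positive rate
  (default 0); a non-yes flag is recorded as missing with a small
  per-source probability (1%, except 5% for ED), carved out of the
  non-yes mass so the yes-probability *is* the sensitivity;
* hospital-stay counts are Poisson with mean
  `stay_intensity × (0.25 + 1.75·min(age, 85)/85)` times cause
  multipliers (cancer 1.6, cardiovascular 1.3, external 0.5) and a
  declining urban→remote gradient — chronic disease and old age mean more
  admissions, remoteness means fewer. The intensities (1.2 stays, 0.8 ED
  attendances at the reference age) were chosen so that linked coverage
  is near-saturated at old ages but materially incomplete at young ages;
  that differential coverage is what produces the characteristic pattern
  of enhancement rising with age, and is the single most consequential
  free choice in the generator;
* stays expand into one to three transfer-linked, date-adjacent episode
  rows, and a person's stays are generated at least 80 days apart, so the
  episode-to-stay collapser can recover the generated structure exactly;
* infant deaths receive perinatal/birth-registration records whose parent
  flags are drawn with the parents sharing the infant's true status;
* finally each record is dropped with the missed-link rate (0.005) and
  re-attached to a uniformly chosen other death with the false-link rate
  (0.004) — the reported linkage quality of the motivating study.

Randomness uses one root seed from which per-stage streams are derived,
so the same configuration is byte-reproducible.

What the generator does **not** emulate: real linkage-field comparison
(linkage quality enters only as error rates), dependence of reporting
errors within a person, age- or remoteness-dependent *death-record*
sensitivity, and family structure beyond the parent-status convenience
above. A green pipeline test therefore establishes internal correctness
— the classifiers, collapser and indicators do what they claim under the
stated error structure — not that real registry data behave like the
generator.

## Validation design

The `recovery_check()` closes the loop analytically: for a true member
with death-record sensitivity $s_0$ and units with yes-probabilities
$p_j$ (for a stay of $m$ episodes, $p = 1-(1-s_{APD})^m$; for an infant
perinatal unit, $1-(1-s_{PDC})^2$),

$$P(\text{at least one}) = 1 - (1 - s_0)\prod_j (1 - p_j),$$

and the algorithm's probability adds, over the $3^n$ tri-state unit
outcomes, the mass passing the $n/k$ thresholds — computed exactly by a
small dynamic programme (itself tested against brute-force enumeration).
Simulated counts must fall within 3 Monte-Carlo standard errors of these
expectations; the check refuses to run unless false-positive and
linkage-error rates are zero, because only there are the closed forms
exact.

## Numerical choices and edge cases

* Rounding everywhere matches printed-table convention: one decimal
  (two for the misclassification rate), half away from zero.
* Median of an empty stratum is `NA`, never 0.
* `percent_increase` refuses a zero baseline rather than returning
  infinity.
* Episode collapsing sorts by admission then discharge date and uses the
  running maximum discharge, so nested episodes and shuffled input order
  cannot change the result.
* The external-cause ICD-10 range starts at V01 exactly; V00 is outside.
  Decimal codes classify by their three-character parent.
* All probabilities are validated into $[0,1]$ before any output is
  generated.

## Limitations

The package evaluates enhancement methods on synthetic data only; it
makes no claim about any real population, and an enhanced count is a
statistical construct for planning and research, not a determination of
any individual's identity. Life-expectancy estimation from enhanced
counts, dataset-specific evidence weights, and the record-linkage engine
itself are out of scope.
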