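---
title: "Spatiotemporal zoning of outbreak news: the scheme, the statistics, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal zoning of outbreak news}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatzone)
```

## The problem

Report-based health surveillance systems (GPHIN, HealthMap, BioCaster and
kin) mine news text for outbreak signals. The common shortcuts — geocode the
first disease/location pair, stamp events with the publication date — break
down exactly where fine-grained surveillance matters: detailed locations and
event dates usually appear later in a story, mixed with historical
background, hypotheticals, and places that are related to the outbreak in
other ways (donor countries, previously affected regions). Spatiotemporal
zoning addresses this by partitioning a news report into *zones*: maximal
runs of consecutive clause-level events that occurred at the same place in
the same time frame. This package implements the zoning data model and
validator, the temporal normalization rules, the zone-boundary algorithm,
an inter-annotator agreement suite for scheme-reliability studies, and a
synthetic corpus generator that makes all of it testable without access to
an annotated news corpus.

## The annotation scheme

The unit of annotation is the **event-predicate**: a verb, predicative
adjective, or prepositional phrase denoting a single event, in the TimeML
sense. Each carries one of four classes:

* `Event_Normal` — a temporally locatable event (happened, ongoing, or will
  definitely happen);
* `Event_Report` — a communicative event ("said", "announced"); kept
  separate because the time of speaking re-anchors the interpretation of
  quoted material;
* `Event_Hypothetical` — possible-world events and predictions;
* `Event_Info` — generic knowledge, requests/imperatives, and copular
  descriptions.

The last two classes cannot be placed on a timeline, so the validator
rejects any temporal attribute on them. Locatable predicates carry six
temporal attributes, all at **day granularity** (outbreak news rarely
supports anything finer, and surveillance systems organize reports by day):

| attribute | meaning | values |
|---|---|---|
| `anchor_val` | reference date for interpretation | ISO date |
| `val` | event time relative to the anchor | `PAST_REF`, `PRESENT_REF`, `FUTURE_REF` |
| `stime`, `etime` | approximate start/end of the occurrence period | ISO date or `PAST`/`PRESENT`/`FUTURE` |
| `stime_dir`, `etime_dir` | relation between the event and the stated time | `AS_OF`, `BEFORE`, `AFTER` |

The direction classes collapse the thirteen fine-grained TimeML
event–time relations onto three (`map_timeml_relation()`): the nine
overlap-like relations onto `AS_OF`, the two before-relations onto
`BEFORE`, the two after-relations onto `AFTER`.

The spatial attribute is a single set of location **surface strings exactly
as they appear in the text** — one attribute suffices because every location
associated with a predicate stands in the same "occurred in" relation.
Grounding to coordinates or identifiers is out of scope here.

### Design choices in the data model

Several points were genuinely open and were fixed as follows:

* **Character spans** are 0-based, half-open intervals over the raw text —
  unambiguous span arithmetic, and the convention of most standoff formats.
* **Unknown locations** on locatable predicates are an *empty* location set,
  not a sentinel string; comparators treat two empty sets as agreement.
  Inventing a null token would silently contaminate string-level comparison.
* **`val` is stored, not derived.** It is an annotated judgement;
  `check_temporal_consistency()` flags contradictions between `val` and
  absolute or symbolic start/end times (by the sign of each time point
  relative to the anchor) but never overwrites them.
* **Direct speech is an explicit link** (`in_direct_speech_of`) to the
  governing Reporting predicate, since speech-scope detection is an upstream
  NLP task. `resolve_anchor()` returns the document date by default and the
  Reporting event's occurrence date inside quoted speech; for *indirect*
  reports the document date applies. A governing Reporting predicate with
  only symbolic time falls back to the document date with a warning.
* **Malformed values are violations, not unrepresentable states**: the
  constructors accept what the annotator wrote, and
  `validate_event_predicate()` / `validate_document()` return violations as
  data, so an annotation tool can hold and display a bad annotation.

## Temporal normalization

`normalize_date()` maps a temporal expression and an anchor date to either
an absolute day or a day-granular period. Absolute formats (`2006-11-08`,
`29 Aug 2008`, `15/8/2009`) parse independently of the anchor. The relative
vocabulary is a deliberately **closed grammar** — `today`/`yesterday`/
`tomorrow`, `<n> days ago`, `last/next <weekday>`, `last/this/next
week|month|year`, a named month with optional year, and `last week of
<month> [<year>]` — because a closed grammar has testable, reviewable
semantics, whereas a heuristic parser fails silently. Anything outside the
grammar raises a normalization error carrying the surface string.

Conventions, fixed once:

* ambiguous numeric dates parse **day-first** (`15/8/2009` is 15 August; a
  `month_first` switch covers US-style sources); two-digit years `<= 68` map
  to 2000s;
* `last <weekday>` is the most recent *strictly earlier* such weekday;
  weeks are ISO 8601 Monday–Sunday weeks, so `this week` is the ISO week
  containing the anchor;
* coarse spans truncate to days by taking the span's first and last day; a
  named month covers the whole month, and `last week of <month>` is the
  month's final seven days (no week-boundary alignment is implied by the
  phrase, and the final-seven-days reading keeps the period inside the
  month);
* times of day, time zones, and durations-as-quantities are out of scope.

Two properties pin the semantics down in the test suite: normalization is
idempotent on its own absolute outputs, and day-offset expressions are
translation-equivariant in the anchor.

## Zone generation

Given fully attributed predicates, zoning is greedy left-to-right merging
over a traversal of the predicates: a predicate joins the current zone iff
it is `attributes_compatible()` with it — same class, same location set,
and, for locatable classes, all six temporal attributes identical — else it
opens a new zone. Because compatibility is exact attribute identity it is an
equivalence relation, so merging is order-independent within a run, every
predicate lands in exactly one zone, adjacent zones are incompatible
(maximality), and re-zoning a zoned sequence is idempotent. These
invariants are asserted over 500 synthetic documents in the test suite.

The default **traversal** visits matrix-clause predicates in textual order
and recurses into each subordinate clause immediately after its governing
predicate (the last matrix predicate starting before the clause); a plain
`"textual"` order is available as an option. Clause nesting is inferred
from span containment. Zones are kept **flat and ordered over the traversal
sequence**; when clauses interleave, zone character spans may overlap, which
is intentional — a zone's span is the minimal interval covering its members'
clause units, and re-zoned subordinate material is *not* folded back into
the parent zone's span (the defensible alternative — letting the matrix
zone's span swallow the subordinate clause it was split from — would make
spans ambiguous about membership).

## Agreement measurement

Event-class assignment is a mutually exclusive four-way classification, so
it is scored with **Cohen's kappa**,

$$\kappa = \frac{\Pr(a) - \Pr(e)}{1 - \Pr(e)},$$

where $\Pr(a)$ is the observed agreement and $\Pr(e)$ the chance agreement
implied by the two annotators' marginal class distributions. The spatial
and temporal attributes are set-valued/composite — the annotator may pick
any location strings from the text — so plain **percentage agreement** under
a task-appropriate comparator is used instead; no chance-corrected statistic
for the set-valued task is attempted:

* `temporal_comparator()` — agreement only when *all six* temporal
  attributes are identical (a symbolic time never equals an absolute date);
* `spatial_exact_comparator()` — location sets equal after normalization
  (case-insensitive, whitespace-collapsed, canonical comma spacing; this
  keeps `"Bangkok, Thailand"` distinct from `"Bangkok"`);
* `spatial_approx_comparator()` — accepts equality, in-order token
  subsequence (`"Bangkok, Thailand"` ~ `"Bangkok"`), or gazetteer
  containment in either direction (`"Tokyo"` within `"Japan"`). The default
  criterion is lenient ("some pair across the two sets matches"), with a
  strict every-location-must-match variant behind `mode = "all"`. Exact
  agreement implies approximate agreement under either mode, so approximate
  percentage agreement never falls below exact — a monotonicity property
  the tests assert on every synthetic corpus.

`per_class_agreement()` stratifies by event class. When the annotators
assign *different* classes to an item the stratum is ambiguous; the package
defaults to annotator 1's class and exposes `stratify_by` to flip it.

The package ships two 4×4 event-class confusion matrices from a published
three-annotator reliability study on 100 outbreak news reports
(`zoning_confusion_matrices()`): 1086 and 908 predicates, kappas of 0.87
and 0.90 at two decimals, with marginal class proportions such as 53.31%
Normal for one annotator. These fixtures anchor the agreement suite to real
numbers end-to-end.

## The synthetic generator and noise model

`generate_corpus()` emulates the *structure* of annotated outbreak news:
a publication date, clause-segmented template sentences, verbatim location
mentions drawn from a hierarchical country > province > city gazetteer,
date mentions recorded as temporal entities, and event-predicates whose
classes are drawn i.i.d. from a configured distribution. Defaults are the
study conditions: the class distribution 53.31 / 23.30 / 5.80 / 17.59
percent over Normal/Reporting/Hypothetical/Information observed for one
annotator on the 1086-predicate set; 6–25 predicates per document
(the bulk of the study's documents); publication dates mid-2005 through
2006. No published rate exists for quoted speech, so `p_direct_speech`
defaults to 0.25, chosen once on the reasoning that roughly a quarter of
predicates are Reporting events and quoted constructions accompany a large
share of them; likewise `p_subordinate = 0.3` for embedded clauses, enough
to exercise nested-clause traversal in every corpus of realistic size.

`simulate_annotator_pair()` perturbs a gold annotation **independently per
annotator** — the same conditional-independence-given-truth structure that
Cohen's $\Pr(e)$ assumes — with three noise channels mirroring the
disagreement modes reliability studies actually report: class relabeling
through a row-stochastic confusion matrix, temporal flips (an absolute date
moved by ±1–3 days, or a direction class swapped, chosen uniformly among
the applicable moves), and partitive location generalization (a location
replaced by its gazetteer parent — the `"Tokyo"` → `"Japan"` pattern).
`expected_kappa()` gives the analytic kappa of that model in closed form,
and `calibrate_noise_for_kappa()` inverts it by root finding, so simulation
studies can target a kappa exactly. The test suite verifies parameter
recovery at κ\* ∈ {0.5, 0.87, 0.90} on 5,000 simulated items, within four
bootstrap standard errors.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: linguistically realistic text (templates, not
news prose), annotator drift or item difficulty (noise is i.i.d. across
items), correlated annotator errors (hard items are hard for everyone in
real studies, which depresses $\Pr(a)$ more than this model predicts),
discourse-level temporal inference, and coreference. The agreement
*machinery* is exercised fully; absolute agreement levels on real corpora
are outside what simulation can certify.

## Numerical and degenerate-input conventions

* Kappa on an empty matrix is an error; `pr_e = 1` (all mass in one
  matching marginal pattern) is a degenerate-marginals error rather than
  `0/0`.
* Percentage agreement over an empty item set is an error, not `NaN`.
* Locations absent from the gazetteer disable the containment criterion for
  that pair only — never an exception.
* Test problem sizes were chosen to make Monte Carlo bounds sharp but keep
  the default suite quick: 1,000 random label-vector pairs (n ≤ 200) for
  oracle equivalence at 10⁻¹², 5,000 items per kappa-recovery target, 500
  documents for the zoning invariants.
* All generation and simulation is bit-reproducible from (configuration,
  seed); noise specifications accept their own seed to isolate one
  annotator's randomness.

## Serialization

The XML dialect is minimal and round-trippable: a `<doc id date>` element
wrapping a `<text>` element whose content is the raw text with inline
`<clause>`, `<ne type="location|time">` and `<ep .../>` elements; all
offsets are recomputed from the markup on read. Zones live standoff under
`<zones>` because their spans may legally overlap. Serialization is
canonical (fixed attribute order, minimal escaping), so
write → read → write is byte-identical — asserted in the tests. A standoff
JSON export (`write_standoff_json()`) is provided for toolchains that
prefer offsets, and a `spatzone` command-line script (in `exec/`) wraps
validation, zoning, statistics, agreement and simulation.

## Known limitations

Upstream NLP (entity recognition, temporal-expression spotting, clause
segmentation, speech-scope detection) is assumed done; the package
validates and processes its output. Source/destination roles of movement
events, event polarity, and geographic grounding are not represented.
Kappa generalizations to more than two annotators (Fleiss) and significance
tests on kappa are out of scope.
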