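---
title: "Methods: dictionary-driven harmonization, quality scoring, and FHIR R4B export"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-driven harmonization, quality scoring, and FHIR R4B export}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoharmonizer)
```

# The problem this package addresses

Multicentre oncology studies collect patient-level clinical variables —
diagnosis and histology codes, receptor status, grading, dosing regimens,
follow-up intervals — from hospitals with heterogeneous record systems. To
make such data usable for pooled analysis and AI model development, three
things must happen between the capture form and the repository:

1. every variable must carry unambiguous semantics (an ontology code from
   SNOMED CT, ICD-O-3, LOINC, RxNorm or NCIT, bound through a controlled
   value set);
2. the arriving rows must be quality-scored so that incomplete,
   non-conformant or implausible records can be flagged before they reach
   downstream consumers; and
3. the rows must be re-expressed in an interoperable exchange structure —
   here, FHIR R4B bundles, one JSON document per patient — with
   pseudonymized identifiers and no calendar dates.

`oncoharmonizer` implements this pipeline end to end, driven by a single
machine-readable *data dictionary* per study schema. The dictionary is the
only place where study-specific knowledge lives; the engine code is generic.

# The data dictionary

One YAML document per schema (see
`oh_example("breast_demo.yaml")`). Each variable declares:

* `datatype` — one of `code`, `integer`, `decimal`, `string`, `interval`,
  `boolean`;
* `requirement_level` — `minimal` (ground-truth fields a record is useless
  without), `mandatory` (enriching model inputs), or `recommended`
  (added-value fields from selected centres);
* for coded variables, a closed `value_set` binding each raw capture-form
  code to an ontology coding. A `sentinel` entry represents the grouped
  category "other"; because an isolated "other" has no interoperable
  meaning, its coding is typically a SNOMED post-coordinated expression
  carried as an opaque string (the package deliberately does not parse
  compositional grammar — the expressions are representation, not
  computation);
* optional `max_length` and `range` constraints feeding the quality rules;
* the target FHIR binding: `resource_kind`, `element_path`, an optional
  `resource_group` (variables sharing a group populate one resource
  instance), and optional `fixed_codings` (e.g. the LOINC code stating what
  an Observation measures).

`load_dictionary()` refuses a schema unless every invariant holds, and
reports *all* violations at once; `validate_dictionary()` exposes the same
checks as data. Terminology release versions (`terminology_versions()`) are
provenance metadata only — no live terminology service is ever consulted.

# The quality model

Quality is assessed along three dimensions, decomposed into six check
types:

| Type            | Dimension    | A check fails when…                          |
|-----------------|--------------|----------------------------------------------|
| `minimal_req`   | Completeness | a minimal-tier cell is missing               |
| `mandatory_req` | Completeness | a minimal- or mandatory-tier cell is missing |
| `length`        | Conformance  | the raw text exceeds the declared cap        |
| `datatype`      | Conformance  | a non-empty cell fails to parse as declared  |
| `permissible`   | Conformance  | a coded cell is outside the value set        |
| `range`         | Plausibility | a parsed number is outside `[min, max]`      |

Three design choices deserve explanation, because the design was genuinely
open:

* **A minimal variable is a fortiori mandatory.** A blank minimal cell
  therefore fails both completeness types. The fault-injection API
  understands this coupling: requested counts are target *fail* counts, and
  `mandatory_req` requests below `minimal_req` are rejected as infeasible.
* **Missing cells trigger only completeness checks.** Conformance and
  plausibility rules are skipped on empty cells, so one blank is attributed
  to exactly one dimension and the total score stays interpretable; a
  missing value never double-counts as a datatype failure too. The same
  single-attribution logic makes an unparseable cell a `datatype` failure
  but not additionally a `range` failure.
* **Datatype rules exist only for parse-constrained datatypes** (`integer`,
  `decimal`, `interval`, `boolean`). A coded or free-text cell is a string
  on disk; any string "parses", so a datatype check there would be
  vacuous — the real conformance checks for those cells are
  `permissible` and `length`. This also means the two conformance counters
  partition the cells instead of overlapping, which is what allows a
  scorecard to show more permissible checks than datatype checks.

The empty string is the only missing marker on disk. `"NA"`/`"NULL"`
synonyms are deliberately not recognized: they fail datatype conformance,
making sloppy missingness visible rather than silently absorbed.

## Scoring

Each check type `i` receives a weight `w_i` (defaults: 50 for
`minimal_req`, 10 for each of the other five; any non-negative split
summing to 100 is accepted). With `p_i` passes out of `n_i` executed
checks, the row score is `w_i * p_i / n_i` and the total score is the sum
of the *unrounded* row scores. Rounding (half-up, two decimals) is applied
only for display, and only once per printed number: rounding each row first
and summing would drift by a cent (in the worked example below, the rounded
rows sum to 89.62 against a true 89.63). A check type that executed zero
checks keeps its full weight — an absent defect class is vacuously
satisfied, and must never penalize a cohort for containing, say, no
range-limited variables. The rejected alternative (renormalizing the
remaining weights) silently changes the meaning of the configured weights.

Per-patient ratings reuse the same formula within one record, with the
dimension's share of the weight budget as the weight. They are reported,
not acted on: the package deliberately applies no automatic exclusion
threshold, leaving the filtering decision to the study.

## The worked scorecard example

The documentation's reference scorecard —

```
Dimension      Type             Fail   Pass  Total  Weight    Score
Completeness   minimal_req         2     16     18      50   44.44%
Completeness   mandatory_req       3     32     35      10    9.14%
Conformance    length              1     10     11      10    9.09%
Conformance    datatype            0     40     40      10   10.00%
Conformance    permissible         3     52     55      10    9.45%
Plausibility   range               1      3      4      10    7.50%
Total:                            10    153    163     100   89.63%
```

— is reproduced end to end by `scorecard_demo_cohort()`, which generates
and fault-injects a *pooled* cohort over two demonstration schemas (4
records of a 21-variable breast schema, 3 records of an 11-variable
colorectal schema). The pooling is forced by arithmetic, not taste:
completeness checks always execute, so a single schema with `m` minimal
and `d` further mandatory variables can only produce completeness totals
`n*m` and `n*(m+d)` — and 18 and 35 share no common divisor. A pooled
cohort is also the realistic reading: a consortium's quality report spans
several use-case schemas. `run_qc()` supports this directly by matching
rules to records on their schema identifier. The injected defects are
placed on free-text variables that carry no conformance rules (for the
blanks) and on otherwise-clean cells (for the rest), so each defect
perturbs exactly one check type and the executed-check totals are
unaffected.

# Pseudonymization

Two transforms remove indirect identifiers:

* **Double-hashed patient identifiers.** `hash_patient_id()` chains two
  keyed SHA-256 stages — `sha256(platform_salt || sha256(site_salt ||
  local_id))` — so the first stage can run at the data provider before
  anything leaves the site, and the platform only ever handles stage-one
  digests. SHA-256 was chosen for ubiquity and testability; the
  construction is deterministic by design (the same patient must map to the
  same platform ID across uploads). Salts are supplied via environment or
  configuration and are never logged. Pseudonymized data remain personal
  data; the package makes no anonymization claim and implements no key
  escrow.
* **Interval-to-epoch date recoding.** Capture forms collect durations
  (`time_interval(value, unit)` with units days/weeks/months), never
  calendar dates. Where a FHIR element accepts a period, the duration is
  emitted as a pseudo-period anchored at 1970-01-01 (`recode_interval()`),
  mimicking the Unix epoch; the span, which is the only real information,
  is exactly preserved. Weeks are exactly 7 days; months are
  calendar-month addition, unambiguous because the anchor is always the
  first of the month. `decode_period()` inverts the transform and refuses
  spans that are not whole numbers of the requested unit rather than
  rounding. The round-trip is property-tested for every value up to
  10 000 in each unit.

# FHIR R4B emission

`map_record_to_bundle()` turns one record into one `collection` bundle:
the Patient resource first, then one resource per `(resource_kind,
resource_group)` in dictionary order, each addressed by a version-4
`urn:uuid` URN and referencing the Patient. Bundle type `collection` was
chosen because the outputs are archival documents destined for a
repository, not server transactions. The URN factory is random by default
and seeded (`make_id_factory(seed)`) for byte-reproducible cohort
transforms.

Element population follows the dictionary: coded cells resolve through
`resolve_code()` (strictly — the ETL aborts on a raw code that QC would
merely have flagged), quantities carry value + unit, durations become
epoch-anchored periods. Status-like elements are stamped from fixed
HL7/FHIR codes (`final`, `completed`, Condition `active`/`confirmed`).

Decisions where the standard leaves gaps:

* **Missing values.** A value-bearing Observation with no value carries the
  standard `dataAbsentReason` coding `not-provided` instead; optional
  elements elsewhere are simply omitted; a resource whose *defining* code
  is missing is not built at all; dosing facts without a medication agent
  are an error.
* **Summarised dosing.** MedicationAdministration is designed for a single
  administration entry, so total cycle count and cumulative dose have no
  native element; they are carried as documented extensions
  (`urn:oncoharmonizer:extension:total-cycles`,
  `urn:oncoharmonizer:extension:cumulative-dose`). One resource is built
  per agent variable in a medication group.
* **Dates.** MedicationAdministration is also the one resource whose
  effective element demands calendar dates rather than durations — this is
  exactly where the epoch recoding surfaces in output (a 4-month interval
  becomes `1970-01-01`/`1970-05-01`).

Build-time structural checking enforces required elements, datatypes and
fixed status codes for the six supported resource kinds — a pragmatic R4B
subset, not full profile conformance. Full `StructureDefinition`
validation is out of scope.

# The independent validator

`validate_bundle()`/`validate_cohort()` re-check emitted bundles against
their own structural tables — resource-type legality, required elements,
primitive shapes, period ordering, URN grammar and uniqueness,
Patient-first/single-Patient structure, reference closure, fixed status
sets, and terminology membership (every coding must appear in the
dictionary's value sets or fixed codings, or in the small built-in
housekeeping sets). The validator intentionally shares no code or
constants with the builders, so the two sides act as mutual oracles: the
test suite asserts both soundness (everything the builder emits on clean
input validates) and sensitivity (a catalogue of single-fault mutations —
dropped required element, dangling reference, out-of-set code, corrupted
date, illegal resource type — each produce at least one error attributed
to the faulty path).

# The synthetic cohort generator

`generate_cohort()` emulates a harmonized row-per-patient oncology table:
coded cells drawn uniformly from value sets, integers and decimals within
declared ranges (0–100 where no range is declared), intervals between 0
and 60 units (a plausible follow-up window), booleans and bounded strings,
and double-hashed demo patient identifiers. Everything is deterministic
under a seed, and the caller's RNG state is left untouched.

What the generator does **not** model: joint distributions. Cells are
independent, so correlation structure between, say, receptor status and
subtype is absent; cohort sizes are small; value-set frequencies are
uniform rather than clinically realistic. Passing tests therefore
demonstrate pipeline correctness — parsing, scoring, transformation,
validation, round-trips — not clinical plausibility of the data, and say
nothing about how real capture errors distribute across variables.

`inject_errors()` plants bookkept defects: blanks for completeness,
non-numeric tokens for datatype, out-of-set codes, overlong strings, and
out-of-range values (by at least one unit). Sites never overlap, the
realization of each defect perturbs exactly one check type, and the
returned log predicts the engine's fail counts exactly — generator and
engine validate each other.

# Numerical and testing choices

* Problem sizes: the property suites use 100 random cohorts of 3–50
  records for engine/oracle equivalence, 4 seeded 8-record cohorts for ETL
  integrity, and exhaustive 0–10 000 sweeps per unit for the epoch
  round-trip; these sizes give full branch coverage of the rule engine and
  builders while keeping the default suite under a minute.
* Rounding is half-up (`round_half_up()`), not banker's rounding, because
  displayed scores are commercial-style percentages; aggregation always
  uses unrounded terms.
* The engine-vs-oracle tests compare *findings*, not just counts: the
  brute-force oracle in the test helpers re-derives per-cell outcomes
  straight from the variable definitions with its own parsing logic.
* Degenerate inputs: empty record lists are a configuration error for
  `run_qc()` but legal for CSV serialization (header-only file); an empty
  bundle directory validates as a warning, not an error; zero-check rule
  types score their full weight.

# Known limitations

* The five production schemas of any real consortium are not public; the
  shipped dictionaries are synthetic, representative rosters, and the
  NCIT/LOINC codes on bespoke demo concepts are illustrative bindings.
* The structural validator covers the profile subset the builders emit,
  not the full R4B specification.
* REDCap checkbox (multi-valued) fields are out of scope; the interchange
  dialect is single-valued raw-code export.
* No statistical outlier detection beyond declared ranges, and no
  automatic record filtering on the quality score.
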