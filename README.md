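# oncoharmonizer

Dictionary-driven harmonization, quality scoring, and FHIR R4B export of
oncology clinical data.

Multicentre cancer studies capture patient-level clinical variables through
REDCap-style forms at many hospitals, then need those rows (i) scored for
data quality before anyone trains a model on them, and (ii) re-expressed as
interoperable, pseudonymized FHIR documents for long-term repository
storage. `oncoharmonizer` is an R toolkit for data managers and platform
engineers running that pipeline:

* **Dictionary model** — one YAML document per study schema binds every
  variable to a datatype, a requirement tier (`minimal` / `mandatory` /
  `recommended`), a value set with ontology codes (SNOMED CT, ICD-O-3,
  LOINC, RxNorm, NCIT, HL7/FHIR), optional length/range constraints, and a
  target FHIR R4B element. The dictionary drives everything downstream.
* **REDCap-dialect CSV interchange** — lenient ingestion (bad cells become
  quality findings, not crashes), strict round-tripping.
* **Quality engine** — three dimensions (Completeness, Conformance,
  Plausibility) decomposed into six check types, with a weighted scorecard.
* **Pseudonymization** — double-hashed patient identifiers
  (`sha256(platform_salt || sha256(site_salt || local_id))`) and
  interval-to-epoch date recoding (durations become pseudo-periods anchored
  at 1970-01-01, so no real calendar date ever leaves the pipeline).
* **FHIR R4B ETL** — one `collection` bundle per patient (Patient,
  Condition, Observation, Procedure, MedicationAdministration,
  DiagnosticReport), `urn:uuid` identities, deterministic JSON output.
* **Independent validator** — re-checks emitted bundles with its own
  structural tables and dictionary-membership terminology checking.
* **Synthetic cohorts** — a seeded generator plus bookkept fault injection,
  so every stage is testable without patient data.

## The quality score

For check type *i* with weight *w<sub>i</sub>* (defaults: 50 for minimal
requirements, 10 for each of the other five; weights must sum to 100),
*p<sub>i</sub>* passes and *f<sub>i</sub>* fails:

```
score_i = w_i * p_i / (p_i + f_i)          (full weight if no check ran)
total   = Σ_i  w_i * p_i / (p_i + f_i)
```

Aggregation uses unrounded terms; only displayed numbers are rounded
(half-up, two decimals). A check type with zero executed checks keeps its
full weight — an absent defect class never penalizes a cohort.

## Worked example

```r
library(oncoharmonizer)

schema <- load_dictionary(oh_example("breast_demo.yaml"))  # 13 variables
recs   <- generate_cohort(schema, 20, seed = 42)           # clean cohort
inj    <- inject_errors(recs, c(minimal_req = 2, permissible = 3, range = 1),
                        schema, seed = 42)                 # bookkept defects
rep    <- run_qc(inj$records, compile_rules(schema))
print(rep)
```

```
Dimension      Type             Fail   Pass  Total  Weight    Score
Completeness   minimal_req         2     58     60      50   48.33%
Completeness   mandatory_req       2    118    120      10    9.83%
Conformance    length              0      0      0      10   10.00%
Conformance    datatype            0    100    100      10   10.00%
Conformance    permissible         3    135    138      10    9.78%
Plausibility   range               1     59     60      10    9.83%
Total:                             8    470    478     100   97.78%
```

Reading the report: the two injected blanks sit in minimal-tier cells, so
they fail both completeness rows (a minimal variable is a fortiori
mandatory); the three out-of-set codes and the one out-of-range value each
fail exactly one conformance/plausibility check; no variable in this schema
carries a length cap, so the `length` row ran zero checks and keeps its
full weight. The total, `50·58/60 + 10·118/120 + 10 + 10 + 10·135/138 +
10·59/60`, prints as 97.78%.

Transforming and validating the clean cohort:

```r
out <- tempfile()
res <- transform_cohort(recs, schema, out, seed = 42)  # 20 bundle files
validate_cohort(out, schema)
#> 20/20 bundles valid
```

Each file is one patient's bundle, named by the double-hashed patient ID:

```json
{
  "resourceType": "Bundle",
  "identifier": {
    "system": "urn:ietf:rfc:3986",
    "value": "urn:uuid:30e44098-49e3-4179-b07f-2e17466358a4"
  },
  "type": "collection",
  "entry": [
    { "fullUrl": "urn:uuid:6d139971-6e82-4858-9aa3-e4de6c04d3a1",
      "resource": { "resourceType": "Patient", ... } },
    ...
  ]
}
```

A collected treatment interval of e.g. `4 months` appears on
MedicationAdministration as `"effectivePeriod": {"start": "1970-01-01",
"end": "1970-05-01"}` — the epoch recoding that stands in for real dates.
Total cycle count and cumulative dose ride on the documented extensions
`urn:oncoharmonizer:extension:total-cycles` and
`urn:oncoharmonizer:extension:cumulative-dose`.

## Command line

A thin shim over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","oncoharmonizer.R",package="oncoharmonizer"))')
Rscript "$CLI" generate  --schema breast_demo.yaml --n 20 --seed 42 --out cohort.csv
Rscript "$CLI" qc        --schema breast_demo.yaml --input cohort.csv --min-score 95
Rscript "$CLI" transform --schema breast_demo.yaml --input cohort.csv --out-dir bundles --seed 42
Rscript "$CLI" validate  --dir bundles --schema breast_demo.yaml
```

Exit codes gate pipelines: `qc --min-score` fails below the threshold, and
`validate` fails on any error-severity finding. Hash salts are read from
`ONCOHARMONIZER_SITE_SALT` / `ONCOHARMONIZER_PLATFORM_SALT`, never from
argv.

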