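# Demonstration data dictionary: breast-cancer use case (synthetic roster).
# One document per schema; 12 study variables plus the hashed patient
# identifier, spanning all six supported FHIR resource kinds.
schema_id: breast_demo
use_cases:
  - breast_subtype_by_proxy
variables:
  - name: patient_id
    role: identifier
    requirement_level: minimal
    datatype: string
    resource_kind: Patient
    element_path: Patient.identifier
  - name: biological_sex
    requirement_level: minimal
    datatype: code
    resource_kind: Patient
    element_path: Patient.gender
    value_set:
      - internal_code: "1"
        label: Female
        system: "http://hl7.org/fhir/administrative-gender"
        code: female
        display: Female
      - internal_code: "2"
        label: Male
        system: "http://hl7.org/fhir/administrative-gender"
        code: male
        display: Male
  - name: case_control
    requirement_level: minimal
    datatype: code
    resource_kind: Condition
    element_path: Condition.code
    resource_group: diagnosis
    value_set:
      - internal_code: "1"
        label: Case (malignant lesion)
        system: "http://snomed.info/sct"
        code: "254837009"
        display: Malignant tumor of breast
      - internal_code: "2"
        label: Control (benign lesion)
        system: "http://snomed.info/sct"
        code: "92691004"
        display: Benign neoplasm of breast
  - name: age_at_diagnosis
    requirement_level: minimal
    datatype: integer
    resource_kind: Condition
    element_path: Condition.onsetAge
    resource_group: diagnosis
    unit: years
    range: [18, 100]
  - name: histology
    requirement_level: mandatory
    datatype: code
    resource_kind: DiagnosticReport
    element_path: DiagnosticReport.conclusionCode
    resource_group: pathology_report
    fixed_codings:
      - path: DiagnosticReport.code
        system: "http://loinc.org"
        code: "22637-3"
        display: Pathology report
    value_set:
      - internal_code: "1"
        label: Ductal carcinoma NOS
        system: "http://terminology.hl7.org/CodeSystem/icd-o-3"
        code: "8500/3"
        display: Infiltrating duct carcinoma NOS
      - internal_code: "2"
        label: Lobular carcinoma NOS
        system: "http://terminology.hl7.org/CodeSystem/icd-o-3"
        code: "8520/3"
        display: Lobular carcinoma NOS
      - internal_code: "OTHER"
        label: Other histology
        sentinel: true
        system: "http://snomed.info/sct"
        code: "128462008:116676008=86049000 |Other malignant histology|"
        display: Other malignant histology (grouped)
  - name: er_status
    requirement_level: mandatory
    datatype: code
    resource_kind: Observation
    element_path: Observation.valueCodeableConcept
    fixed_codings:
      - path: Observation.code
        system: "http://loinc.org"
        code: "16112-5"
        display: Estrogen receptor Ag [Presence] in Tissue
    value_set:
      - internal_code: "1"
        label: Positive
        system: "http://snomed.info/sct"
        code: "10828004"
        display: Positive
      - internal_code: "2"
        label: Negative
        system: "http://snomed.info/sct"
        code: "260385009"
        display: Negative
  - name: tumor_grade
    requirement_level: mandatory
    datatype: code
    resource_kind: Observation
    element_path: Observation.valueCodeableConcept
    fixed_codings:
      - path: Observation.code
        system: "http://loinc.org"
        code: "33732-9"
        display: Histology grade
    value_set:
      - internal_code: "1"
        label: Grade 1 on a scale of 1 to 3
        system: "http://snomed.info/sct"
        code: "54102005"
        display: G1 grade
      - internal_code: "2"
        label: Grade 2 on a scale of 1 to 3
        system: "http://snomed.info/sct"
        code: "1663004"
        display: G2 grade
      - internal_code: "3"
        label: Grade 3 on a scale of 1 to 3
        system: "http://snomed.info/sct"
        code: "61026006"
        display: G3 grade
  - name: ki67_percent
    requirement_level: recommended
    datatype: decimal
    resource_kind: Observation
    element_path: Observation.valueQuantity
    unit: "%"
    range: [0, 100]
    fixed_codings:
      - path: Observation.code
        system: "http://loinc.org"
        code: "85319-2"
        display: Ki-67 nuclear Ag [Presence] in Tissue
  - name: surgery_type
    requirement_level: recommended
    datatype: code
    resource_kind: Procedure
    element_path: Procedure.code
    resource_group: surgery
    value_set:
      - internal_code: "1"
        label: Mastectomy
        system: "http://snomed.info/sct"
        code: "69031006"
        display: Excision of breast tissue
      - internal_code: "2"
        label: Breast-conserving surgery
        system: "http://snomed.info/sct"
        code: "392021009"
        display: Lumpectomy of breast
  - name: time_to_surgery
    requirement_level: recommended
    datatype: interval
    resource_kind: Procedure
    element_path: Procedure.performedPeriod
    resource_group: surgery
  - name: chemo_agent
    requirement_level: recommended
    datatype: code
    resource_kind: MedicationAdministration
    element_path: MedicationAdministration.medicationCodeableConcept
    resource_group: neoadjuvant_chemo
    value_set:
      - internal_code: "1"
        label: Doxorubicin
        system: "http://www.nlm.nih.gov/research/umls/rxnorm"
        code: "3639"
        display: Doxorubicin
      - internal_code: "2"
        label: Paclitaxel
        system: "http://www.nlm.nih.gov/research/umls/rxnorm"
        code: "56946"
        display: Paclitaxel
  - name: chemo_cycles
    requirement_level: recommended
    datatype: integer
    resource_kind: MedicationAdministration
    element_path: MedicationAdministration.extension.totalCycles
    resource_group: neoadjuvant_chemo
    range: [1, 12]
  - name: treatment_interval
    requirement_level: recommended
    datatype: interval
    resource_kind: MedicationAdministration
    element_path: MedicationAdministration.effectivePeriod
    resource_group: neoadjuvant_chemo
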