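# Diagnosis code lists mapping register diagnosis columns to diseases.
# Both primary and secondary diagnoses, and underlying and contributing
# causes of death, count; a first-ever code before the study start
# excludes the person from that disease's study population.
AMI:
  name: acute myocardial infarction
  icd8: ["410"]
  icd10: ["I21"]
stroke:
  name: stroke
  icd8: ["430", "431", "433", "434", "436"]
  icd10: ["I60", "I61", "I63", "I649"]
AF:
  name: atrial fibrillation
  icd8: ["42793", "42794"]
  icd10: ["I48"]
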