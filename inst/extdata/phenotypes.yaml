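# Representative phenotype definitions (code prefixes per ICD revision).
- name: bpd
  domain: psychiatric
  icd9: ["301D", "301J"]
  icd10: ["F60.3"]
- name: depression
  domain: psychiatric
  icd9: ["311"]
  icd10: ["F32", "F33"]
- name: adhd
  domain: psychiatric
  icd9: ["314"]
  icd10: ["F90"]
- name: sleep_disorder
  domain: somatic
  icd9: ["307F", "780G"]
  icd10: ["F51", "G47"]
- name: pcos
  domain: somatic
  female_only: true
  icd9: ["256E"]
  icd10: ["E28.2"]
- name: self_harm
  domain: behavioral
  icd9: ["E95"]
  icd10: ["X6", "X7", "X80", "X81", "X82", "X84"]
- name: suicide
  domain: behavioral
  cause_of_death_source: true
  icd9: ["E95"]
  icd10: ["X6", "X7", "X80", "X81", "X82", "X84"]
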