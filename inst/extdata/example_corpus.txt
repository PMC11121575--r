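PMID- 900001
TI  - Cognitive decline and vascular risk in an ageing cohort.
MH  - *Alzheimer Disease/epidemiology
MH  - Dementia/complications
MH  - Hypertension
MH  - Comorbidity
MH  - Humans

PMID- 900002
TI  - Shared neuropathology across neurodegenerative disorders.
MH  - Alzheimer Disease/genetics
MH  - Parkinson Disease
MH  - Comorbidity

PMID- 900003
TI  - Metabolic comorbidity in dementia care.
MH  - *Alzheimer Disease
MH  - Diabetes Mellitus, Type 2/epidemiology
MH  - Dementia
MH  - Comorbidity

PMID- 900004
TI  - Trisomy 21 and early-onset neurodegeneration.
MH  - Alzheimer Disease
MH  - Down Syndrome/genetics
MH  - Comorbidity

PMID- 900005
TI  - A methods note without disease co-mentions.
MH  - Alzheimer Disease
MH  - Comorbidity

PMID- 900006
TI  - Dementia epidemiology without the index disease.
MH  - Dementia
MH  - Comorbidity
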