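term	category
Alzheimer Disease	Nervous System Diseases
Dementia	Nervous System Diseases
Dementia	Mental Disorders
Diabetes Mellitus, Type 2	Nutritional and Metabolic Diseases
Hypertension	Cardiovascular Diseases
Parkinson Disease	Nervous System Diseases
Down Syndrome	Congenital, Hereditary, and Neonatal Diseases and Abnormalities
Foot Rot	Animal Diseases
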