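term	parent
BREAST CANCER	CANCER
LUNG CANCER	CANCER
GLIOBLASTOMA	BRAIN CANCER
BRAIN CANCER	CANCER
ALS	NEURODEGENERATIVE DISEASE
PARKINSON DISEASE	NEURODEGENERATIVE DISEASE
ALZHEIMER DISEASE	NEURODEGENERATIVE DISEASE
HIV	INFECTIOUS DISEASE
TUBERCULOSIS	INFECTIOUS DISEASE
MALARIA	INFECTIOUS DISEASE
TYPE 2 DIABETES	DIABETES
TYPE 1 DIABETES	DIABETES
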