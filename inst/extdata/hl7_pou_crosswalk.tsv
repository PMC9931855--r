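consent_code	target_system	target_id	target_name	fidelity	caution
GRU	HL7_POU	HRESCH	healthcare research	broader	Interpretation, not a stated equivalence: HRESCH spans biomedical, population origin or ancestry, translational and disease/discipline/specialty healthcare research, so it is broader than GRU(CC)
HMB	HL7_POU	BIOHRCH	biomedical research	exact
DS	HL7_POU	DSHRCH	disease specific healthcare research	exact
RS	HL7_POU	DISHRCH	discipline specific healthcare research	related	DISHRCH can be equivalent to RS-[XX], TDS-[XX], or GSO Consent Codes; the inverse mapping is ambiguous
TDS	HL7_POU	DISHRCH	discipline specific healthcare research	related	DISHRCH can be equivalent to RS-[XX], TDS-[XX], or GSO Consent Codes; the inverse mapping is ambiguous
GSO	HL7_POU	DISHRCH	discipline specific healthcare research	related	DISHRCH can be equivalent to RS-[XX], TDS-[XX], or GSO Consent Codes; the inverse mapping is ambiguous
HPOA	HL7_POU	POAHRCH	population origins or ancestry healthcare research	exact
	HL7_POU	CLINTRCH	clinical trial research	none	No Consent Code equivalence stated
	HL7_POU	CLINTRCHNPC	clinical trial research without patient care	none	No Consent Code equivalence stated
	HL7_POU	CLINTRCHPC	clinical trial research with patient care	none	No Consent Code equivalence stated
	HL7_POU	PRECLINTRCH	preclinical trial research	none	No Consent Code equivalence stated
	HL7_POU	TRANSHRCH	translational healthcare research	none	No Consent Code equivalence stated
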