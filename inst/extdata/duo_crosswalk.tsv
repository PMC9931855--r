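consent_code	target_system	target_id	fidelity	caution
NRES	DUO	DUO:0000004	exact
GRU	DUO	DUO:0000005	exact	Attn: not to be confused with the much broader GRU DUO term DUO:0000042
HMB	DUO	DUO:0000006	exact
DS	DUO	DUO:0000007	exact
POA	DUO	DUO:0000011	exact
TDS	DUO		none
RS	DUO	DUO:0000012	exact
NDS	DUO		none
HPOA	DUO		none
NMDS	DUO		none	Attn: The DUO NMDS term DUO:0000015 prohibits any methods development research
RUO	DUO	DUO:0000014	exact
GSO	DUO	DUO:0000016	exact
NPU	DUO	DUO:0000045	exact
NCU	DUO		none	Attn: The DUO NCU term DUO:0000046 defines non-commercial use as data can be used by commercial organisations for research purposes, but not commercial purposes.
BEN	DUO		none
PUB	DUO	DUO:0000019	exact
COL	DUO	DUO:0000020	exact
ROR	DUO		none
RTN	DUO	DUO:0000029	exact
IRB	DUO	DUO:0000021	exact
GS	DUO	DUO:0000022	exact
MOR	DUO	DUO:0000024	exact
TS	DUO	DUO:0000025	exact
OS	DUO		none
US	DUO	DUO:0000026	exact
PS	DUO	DUO:0000027	exact
IS	DUO	DUO:0000028	exact
CQ	DUO		none
CS	DUO		none
CR	DUO		none
HR	DUO		none
ARA	DUO		none
GEN	DUO		none
CL	DUO		none
	DUO	DUO:0000042	none	General research use DUO term, broader than the GRU(CC) Consent Code (which maps to DUO:0000005)
	DUO	DUO:0000015	none	DUO no-methods-development term; prohibits any methods development research, whereas NMDS permits it within the bounds of other data use limitations
	DUO	DUO:0000046	none	DUO non-commercial-use term; permits use by commercial organisations for research (non-commercial) purposes, a narrower prohibition than the NCU Consent Code
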