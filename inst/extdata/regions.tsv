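region	member
EU	AT
EU	BE
EU	BG
EU	HR
EU	CY
EU	CZ
EU	DK
EU	EE
EU	FI
EU	FR
EU	DE
EU	GR
EU	HU
EU	IE
EU	IT
EU	LV
EU	LT
EU	LU
EU	MT
EU	NL
EU	PL
EU	PT
EU	RO
EU	SK
EU	SI
EU	ES
EU	SE
EEA	AT
EEA	BE
EEA	BG
EEA	HR
EEA	CY
EEA	CZ
EEA	DK
EEA	EE
EEA	FI
EEA	FR
EEA	DE
EEA	GR
EEA	HU
EEA	IE
EEA	IS
EEA	IT
EEA	LI
EEA	LV
EEA	LT
EEA	LU
EEA	MT
EEA	NL
EEA	NO
EEA	PL
EEA	PT
EEA	RO
EEA	SK
EEA	SI
EEA	ES
EEA	SE
UK	GB
NORTH_AMERICA	CA
NORTH_AMERICA	MX
NORTH_AMERICA	US
AFRICA	BF
AFRICA	BW
AFRICA	CM
AFRICA	EG
AFRICA	ET
AFRICA	GH
AFRICA	KE
AFRICA	MA
AFRICA	ML
AFRICA	MW
AFRICA	NE
AFRICA	NG
AFRICA	RW
AFRICA	SD
AFRICA	SN
AFRICA	TN
AFRICA	TZ
AFRICA	UG
AFRICA	ZA
AFRICA	ZM
AFRICA	ZW
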