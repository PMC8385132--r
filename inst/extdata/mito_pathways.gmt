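BCAA_DEGRADATION	KEGG valine, leucine and isoleucine degradation (curated)	ABAT	ACAA1	ACAA2	ACAD8	ACADM	ACADS	ACADSB	ACAT1	ACAT2	ALDH1B1	ALDH2	ALDH3A2	ALDH6A1	ALDH7A1	ALDH9A1	AOX1	AUH	BCAT1	BCAT2	BCKDHA	BCKDHB	DBT	DLD	ECHS1	EHHADH	HADH	HADHA	HADHB	HIBADH	HIBCH	HMGCL	HMGCS1	HMGCS2	HSD17B10	IVD	MCCC1	MCCC2	MUT	OXCT1	OXCT2	PCCA	PCCB
BIOTIN_CARBOXYLASES	human biotin-dependent carboxylases (manually defined)	ACACA	ACACB	PC	PCCA	PCCB	MCCC1	MCCC2
PROPANOATE_METABOLISM	KEGG propanoate metabolism (curated)	ABAT	ACACA	ACACB	ACADM	ACAT1	ACAT2	ACSS1	ACSS2	ACSS3	ALDH1B1	ALDH2	ALDH3A2	ALDH6A1	ALDH7A1	ALDH9A1	ECHS1	EHHADH	HADHA	HIBCH	LDHA	LDHB	MCEE	MLYCD	MUT	PCCA	PCCB	SUCLA2	SUCLG1	SUCLG2
BUTANOATE_METABOLISM	KEGG butanoate metabolism (curated)	AACS	ABAT	ACADS	ACAT1	ACAT2	ACSM3	AKR1B10	ALDH1B1	ALDH2	ALDH3A2	ALDH5A1	ALDH7A1	ALDH9A1	BDH1	BDH2	ECHS1	EHHADH	GAD1	GAD2	HADH	HMGCL	HMGCS1	HMGCS2	L2HGDH	OXCT1	OXCT2	PDHA1	PDHA2	PDHB	SDS
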