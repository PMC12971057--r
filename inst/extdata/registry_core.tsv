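profile	cutoff	category	role
Condensation	20	NRPS-core	core
AMP-binding	20	NRPS-core	core
VibH_like	200	NRPS-domain-marker	marker
Cy_tandem	200	NRPS-domain-marker	marker
EntA	200	catechol	marker
EntC	200	catechol	marker
IPL	100	salicylate	marker
SalSyn	250	salicylate	marker
Orn_monoox	150	hydroxamate	marker
Lys_monoox	150	hydroxamate	marker
VbsL	200	hydroxamate	marker
KtzT	150	negative-constraint	negative
MetRS-like	150	negative-constraint	negative
TBH_Asp	150	beta-OHAsp	marker
IBH_Asp	150	beta-OHAsp	marker
SBH_Asp	150	negative-constraint	negative
CyanoBH_Asp1	150	beta-OHAsp	marker
CyanoBH_Asp2	150	beta-OHAsp	marker
IBH_His	150	beta-OHHis	marker
GrbD	150	graminine	marker
GrbE	150	graminine	marker
FbnL	150	Dmaq	marker
FbnM	150	Dmaq	marker
PvdO	150	pyoverdine-chromophore	marker
PvdP	250	pyoverdine-chromophore	marker
PF00593	25	transporter	transporter
PF01032	25	transporter	transporter
PF01497	25	transporter	transporter
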