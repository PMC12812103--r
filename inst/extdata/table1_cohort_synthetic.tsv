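patient_id	family_id	family_type	age_at_dx	histology	is_index
WI207-III.1	WI207	tumor_family	.	other_glioma	true
WI166-III.1	WI166	tumor_family	.	other_glioma	true
WI14-III.1	WI14	tumor_family	.	other_glioma	true
WI60-III.1	WI60	tumor_family	.	other_glioma	true
WI226-III.1	WI226	tumor_family	.	other_glioma	true
WI175-III.1	WI175	tumor_family	.	other_glioma	true
WI86-III.1	WI86	tumor_family	.	other_glioma	true
WI04-III.1	WI04	tumor_family	.	other_glioma	true
WI191-III.1	WI191	tumor_family	.	other_glioma	true
WI165-III.1	WI165	tumor_family	.	other_glioma	true
WI50-III.1	WI50	tumor_family	.	other_glioma	true
WI209-III.1	WI209	tumor_family	.	other_glioma	true
WI205-III.1	WI205	tumor_family	.	other_glioma	true
WI214-III.1	WI214	tumor_family	.	other_glioma	true
WI09-III.1	WI09	tumor_family	.	other_glioma	true
WI75-III.1	WI75	tumor_family	.	other_glioma	true
WI48-III.1	WI48	tumor_family	.	other_glioma	true
WI49-III.1	WI49	tumor_family	.	other_glioma	true
WI70-III.1	WI70	tumor_family	.	other_glioma	true
Fam003-III.1	Fam003	tumor_family	.	other_glioma	true
WI78-III.1	WI78	tumor_family	.	other_glioma	true
LI06-III.1	LI06	tumor_family	.	other_glioma	true
WI87-III.1	WI87	tumor_family	.	other_glioma	true
WI105-III.1	WI105	tumor_family	.	other_glioma	true
WI160-III.1	WI160	tumor_family	.	other_glioma	true
WI72-III.1	WI72	tumor_family	.	other_glioma	true
WI53-III.1	WI53	tumor_family	.	other_glioma	true
WI222-III.1	WI222	tumor_family	.	other_glioma	true
WI22-III.2	WI22	tumor_family	.	other_glioma	true
WI88-III.1	WI88	tumor_family	.	other_glioma	true
WI183-III.1	WI183	tumor_family	.	other_glioma	true
WI99-III.1	WI99	tumor_family	.	other_glioma	true
WI89-III.1	WI89	tumor_family	.	other_glioma	true
WI37-III.1	WI37	tumor_family	.	other_glioma	true
Fam004-III.1	Fam004	tumor_family	.	other_glioma	true
Fam002-II.2	Fam002	tumor_family	.	other_glioma	true
Fam002-III.1	Fam002	tumor_family	.	other_glioma	false
Fam002-III.2	Fam002	tumor_family	.	other_glioma	false
WI239-III.1	WI239	tumor_family	.	other_glioma	true
WI61-III.1	WI61	tumor_family	.	other_glioma	true
WI201-III.1	WI201	tumor_family	.	other_glioma	true
WI177-II.1	WI177	tumor_family	.	other_glioma	true
WI33-III.1	WI33	tumor_family	.	other_glioma	true
WI153-III.1	WI153	tumor_family	.	other_glioma	true
WI169-II.2	WI169	tumor_family	.	other_glioma	true
WI11-III.1	WI11	tumor_family	.	other_glioma	true
WI103-III.1	WI103	tumor_family	.	other_glioma	true
WI51-III.1	WI51	tumor_family	.	other_glioma	true
WI236-III.1	WI236	tumor_family	.	other_glioma	true
WI122-III.1	WI122	tumor_family	.	other_glioma	true
WI163-III.1	WI163	tumor_family	.	other_glioma	true
WI126-II.2	WI126	tumor_family	.	other_glioma	true
WI106-III.1	WI106	tumor_family	.	other_glioma	true
Fam016-III.1	Fam016	tumor_family	.	other_glioma	true
WI145-III.1	WI145	tumor_family	.	other_glioma	true
WI08-III.1	WI08	tumor_family	.	other_glioma	true
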