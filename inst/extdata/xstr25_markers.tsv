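name	chrom	start	end	linkage_group
DXS10135	chrX	9338348	9338348	LG1
DXS8378	chrX	9402208	9402208	LG1
DXSF02	chrX	9431066	9431066	LG1
DXSF07	chrX	35252634	35252634	LG2
DXSF08	chrX	35272602	35272602	LG2
DXSF09	chrX	35513419	35513419	LG2
DXS10079	chrX	67460598	67460598	LG3
DXSF13	chrX	67519652	67519652	LG3
DXS10074	chrX	67757308	67757308	LG3
DXS10075	chrX	67778377	67778377	LG3
DXSF15	chrX	87064146	87064146	LG4
DXS6803	chrX	87176189	87176189	LG4
DXSF18	chrX	87326280	87326280	LG4
DXSF19	chrX	87611620	87611620	LG4
DXSF28	chrX	115397284	115397284	LG5
DXSF29	chrX	115435046	115435046	LG5
DXSF33	chrX	116381329	116381329	LG5
DXS10103	chrX	134284939	134284939	LG6
DXS10102	chrX	134406092	134406092	LG6
HPRTB	chrX	134481523	134481523	LG6
DXS10101	chrX	134520504	134520504	LG6
DXS10146	chrX	150403859	150403859	LG7
DXS10134	chrX	150481858	150481858	LG7
DXS10147	chrX	150495165	150495165	LG7
DXS7423	chrX	150542233	150542233	LG7
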