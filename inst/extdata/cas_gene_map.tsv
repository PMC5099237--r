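accession	cas_name
COG1518	cas1
TIGR00287	cas1
PF01867	cas1
COG1343	cas2
TIGR01573	cas2
PF09827	cas2
COG3512	cas2-homolog
COG1203	cas3
TIGR01587	cas3
TIGR01596	cas3
PF18019	cas3
COG1468	cas4
TIGR00372	cas4
PF01930	cas4
COG1688	cas5
TIGR02593	cas5
COG1583	cas6
TIGR01877	cas6
PF10040	cas6
COG1857	cas7
TIGR02590	cas7
COG2254	cas8
TIGR02547	cas8
TIGR01865	cas9
PF13395	cas9
COG1353	cas10
TIGR02577	cas10
TIGR02578	cas10
COG1337	csm3
COG1604	cmr4
TIGR02581	csx1
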