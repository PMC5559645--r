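gene	role	hotspot_pos	hotspot_count	canonical	splice_site
PIK3CA	oncogene	178936091	120	TRUE	FALSE
PIK3CA	oncogene	178952085	95	TRUE	FALSE
ESR1	oncogene	152419923	12	FALSE	FALSE
TP53	TSG	7577120	85	TRUE	FALSE
TP53	TSG	7578406	40	FALSE	FALSE
GATA3	TSG	8111433	6	FALSE	TRUE
ARID1A	TSG	27100181	3	FALSE	FALSE
JAK2	TSG	5078395	2	FALSE	FALSE
STAT3	TSG	40474420	2	FALSE	FALSE
CCND1	oncogene	69462910	8	FALSE	FALSE
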