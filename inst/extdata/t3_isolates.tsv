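id	length_bp	name
NC_48862	11600	Salmonella phage astrithr
NC_002515	11700	Mycoplasma virus P1
NC_016651	14300	Rhodococcus phage RRH1
NC_002670	14500	Lactococcus phage bIL311
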