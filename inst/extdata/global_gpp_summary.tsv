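model	gpp_mean	gpp_sd
IBIS	107.50	1.37
EC-LUE	109.39	1.48
IBIS-Type	123.97	1.76
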