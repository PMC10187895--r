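sample_id	target	reference	ct_target	ct_reference	replicate
topAtopB_like	ydcM	lepA	17.52	19.03	ng50
topAtopB_like	ydcM	lepA	16.61	18.06	ng100
topAtopB_like	qseC	lepA	16.74	19.03	ng50
topAtopB_like	qseC	lepA	15.79	18.06	ng100
topA_like	ydcM	lepA	18.77	19.01	ng50
topA_like	ydcM	lepA	17.73	18.04	ng100
topA_like	qseC	lepA	18.63	19.01	ng50
topA_like	qseC	lepA	17.68	18.04	ng100
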