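application	flow_min	flow_max	units	reference
Intracerebral injection in mice	0	0.1	ul/min	B6
Murine inner ear drug delivery	0.01	0.1	ul/min	B26
Drug delivery system for the renal medulla in rats	0.016	0.5	ul/min	B27
Convection-enhanced delivery to striatum in rats	0.1	5	ul/min	B8
Intracerebroventricular injection of cells in mice	1	1	ul/min	B28
Optofluidic drug delivery system for the peripheral nerves	1.5	1.5	ul/min	B11
Optofluidic drug delivery system for the brain	0.1	2.5	ul/min	B10
Convection-enhanced delivery in the brain of cats	0.5	4	ul/min	B15
Focal delivery in the brain	0.03	5	ul/min	B9
Optofluidic drug delivery system for the brain (high rate)	5.2	5.2	ul/min	B29
Lymphatic drug delivery system	10	80	ul/min	B30
Intra-arterial drug delivery in rat brain tumor	17	200	ul/min	B7
Drug delivery system for transdermal delivery	63	520	ul/min	B31
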