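name	variant	ddg_kcal_mol
C1	S7C/K63N/A99E/K113R	-0.00256648
C2	S7C/K63N/A99T/K113R	-0.101781
N1	S7N/K63N/A99C/K113R	-0.202330
N2	S7N/K63N/A99E/K113E	-0.0948427
N3	S7N/K63N/A99E/K113R	-0.543583
N4	S7N/K63N/A99T/K113R	-0.388018
N5	S7N/K63N/A99V/K113R	-0.241144
Y1	S7Y/K63N/A99E/K113R	-0.121693
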