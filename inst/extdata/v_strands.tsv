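# V-domain beta strands (9) with their IMGT position ranges and the sheet
# each strand belongs to in the two-layer display. The per-strand ranges
# are the package's standard approximation of the Collier de Perles
# layout; sheet_order gives the left-to-right column order within a sheet.
strand	start	end	sheet	sheet_order
A	1	15	back	1
B	16	26	back	2
C	39	46	front	3
C'	47	55	front	4
C''	66	74	front	5
D	75	84	back	4
E	85	96	back	3
F	97	104	front	2
G	118	128	front	1
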