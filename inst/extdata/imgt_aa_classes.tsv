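# IMGT amino acid classes of the 20 common amino acids.
# One record per residue: one-letter code, hydropathy class (3 classes),
# volume class (5 classes), physicochemical class (11 classes).
# Each of the three columns partitions the 20 residues.
residue	hydropathy	volume	physicochemical
A	hydrophobic	very_small	alanine
C	hydrophobic	small	cysteine
D	hydrophilic	small	acidic
E	hydrophilic	medium	acidic
F	hydrophobic	large	aromatic
G	neutral	very_small	glycine
H	neutral	medium	histidine
I	hydrophobic	medium	aliphatic
K	hydrophilic	medium	basic
L	hydrophobic	medium	aliphatic
M	hydrophobic	medium	methionine
N	hydrophilic	small	polar
P	neutral	small	proline
Q	hydrophilic	medium	polar
R	hydrophilic	large	basic
S	neutral	very_small	polar
T	neutral	small	polar
V	hydrophobic	medium	aliphatic
W	hydrophobic	very_large	aromatic
Y	neutral	large	aromatic
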