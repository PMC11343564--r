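MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF E-box
# Synthetic stand-in centred on the CACGTG consensus (MYC/MYCN class) with
# weakly informative flanks; not a curated database matrix.
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.250 0.350 0.200 0.200
 0.150 0.550 0.150 0.150
 0.050 0.850 0.050 0.050
 0.850 0.050 0.050 0.050
 0.050 0.850 0.050 0.050
 0.050 0.050 0.850 0.050
 0.050 0.050 0.050 0.850
 0.050 0.050 0.850 0.050
 0.200 0.200 0.400 0.200
 0.200 0.350 0.250 0.200

MOTIF B-box
# Synthetic stand-in for the internal RNA-polymerase-III promoter B-box
# (GTTCGAANNC consensus); not a curated database matrix.
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.050 0.050 0.850 0.050
 0.050 0.050 0.050 0.850
 0.050 0.050 0.050 0.850
 0.050 0.850 0.050 0.050
 0.050 0.050 0.850 0.050
 0.850 0.050 0.050 0.050
 0.850 0.050 0.050 0.050
 0.250 0.250 0.250 0.250
 0.250 0.250 0.250 0.250
 0.050 0.850 0.050 0.050

MOTIF A-box
# Synthetic stand-in for the internal RNA-polymerase-III promoter A-box
# (TRGCNNARYNNG consensus); not a curated database matrix.
letter-probability matrix: alength= 4 w= 12 nsites= 20 E= 0
 0.050 0.050 0.050 0.850
 0.450 0.050 0.450 0.050
 0.050 0.050 0.850 0.050
 0.050 0.850 0.050 0.050
 0.250 0.250 0.250 0.250
 0.250 0.250 0.250 0.250
 0.850 0.050 0.050 0.050
 0.450 0.050 0.450 0.050
 0.050 0.450 0.050 0.450
 0.250 0.250 0.250 0.250
 0.250 0.250 0.250 0.250
 0.050 0.050 0.850 0.050
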