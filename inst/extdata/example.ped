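# Three-generation family with a first-cousin union (X1 x Y1) and a
# second family demonstrating multi-family PED files.
LOOP G1 0 0 1 1
LOOP G2 0 0 2 1 deceased
LOOP A1 G1 G2 1 1
LOOP B1 G1 G2 2 1
LOOP A2 0 0 2 1
LOOP B2 0 0 1 1
LOOP X1 A1 A2 1 1
LOOP Y1 B2 B1 2 1
LOOP K1 X1 Y1 1 2 proband
TRIO F1 0 0 1 1 consanguineous_partner
TRIO M1 0 0 2 1
TRIO C1 F1 M1 2 2
TRIO C2 F1 M1 1 1
TRIO C3 F1 M1 2 1
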