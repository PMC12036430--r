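node_a	kind_a	node_b	kind_b	source
D1	drug	G1	gene	dbA
D1	drug	G2	gene	dbA
D1	drug	G3	gene	dbB
D2	drug	G1	gene	dbA
D2	drug	G4	gene	dbB
D3	drug	G4	gene	dbA
D3	drug	G5	gene	dbC
D4	drug	G5	gene	dbA
D4	drug	G6	gene	dbB
D5	drug	G6	gene	dbC
D5	drug	G7	gene	dbA
D6	drug	G7	gene	dbB
D6	drug	G8	gene	dbA
D2	drug	G8	gene	dbC
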