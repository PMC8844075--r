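# Approximate TM helix ranges for the human neuropeptide Y1 receptor,
# chain A, residues as deposited. Spans are centered on the generic .50
# anchor positions implied by published residue/generic-number pairs
# (e.g. 3.32=Q120 => 3.50=R138; 6.48=W276). Override with your own table
# (e.g. from deposited HELIX records) for exact boundaries.
helix_id	chain	start	end
1	A	29	58
2	A	74	102
3	A	110	143
4	A	150	180
5	A	205	240
6	A	256	291
7	A	296	323
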