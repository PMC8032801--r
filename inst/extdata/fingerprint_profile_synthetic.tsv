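# Synthetic fingerprint-motif profile: column indices refer to positions
# in the companion anchor sequence (fingerprint_anchor_synthetic.fasta).
# The two critical columns carry Y/W in TAARs and N/S in jawed-fish TARLs;
# the remaining motif columns are conserved across all classes. The real
# motif columns are published only graphically, so this profile is a
# curated synthetic stand-in with the same rule structure.
column_index	residue_taar	residue_tarl_jawed	is_critical
300	N	N	FALSE
301	S	S	FALSE
302	L	L	FALSE
303	G	G	FALSE
304	Y	N	TRUE
305	P	P	FALSE
306	W	S	TRUE
307	F	F	FALSE
308	R	R	FALSE
309	K	K	FALSE
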