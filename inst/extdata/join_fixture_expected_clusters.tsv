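chain	cluster_id	n_atoms	n_residues	cavity_participation	mean_cavity_area	max_cavity_area	mean_rvet	median_rvet	n_scored_residues
fixA	0	10	5	2	185	250	30	30	5
fixA	1	10	5	1	120	120	80	80	5
fixA	2	10	5	0	NA	NA	130	130	5
fixA	3	4	2	1	80	80	165	165	2
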