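chain	cavity_id	surface_area	n_residues	n_rigid_clusters	n_rigid_atoms	pct_rigid_atoms_in_cavity	mean_rvet	median_rvet	n_scored_residues	no_clusters
fixA	1	250	4	1	8	80	25	25	4	FALSE
fixA	2	120	4	2	7	35	45	45	4	FALSE
fixA	3	80	1	1	2	50	160	160	1	FALSE
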