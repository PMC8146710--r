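strain_id	family	habitat	genome_bp	gc_pct	shape	length_um	width_um	doubling_h
demo1	Desulfovibrionaceae	freshwater	3600000	63.2	rod	2.5	0.8	6
demo2	Peptococcaceae	soil	4300000	41.8	rod	4.0	1.5	30
demo3	Desulfobulbaceae	marine	3100000	50.5	ovoid	1.8	1.2	10
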