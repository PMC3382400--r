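reference_id	position	expected	role	scheme
mouse_eIF4E	56	W	cap	mouse_eIF4E
mouse_eIF4E	102	W	cap	mouse_eIF4E
mouse_eIF4E	166	W	cap	mouse_eIF4E
mouse_eIF4E	209	S	phospho	mouse_eIF4E
human_eIF4E	43	W	class_diagnostic	human_eIF4E
human_eIF4E	56	W	class_diagnostic	human_eIF4E
dmel_eIF4E-1	251	S	phospho	dmel_eIF4E1
dmel_eIF4E-1	174	L	scaffold_binding	dmel_eIF4E1
dmel_eIF4E-3	103	W	scaffold_binding	family_local
dmel_eIF4E-3	160	L	scaffold_binding	family_local
dmel_eIF4E-4	160	E	scaffold_binding	family_local
dmel_eIF4E-6	33	H	scaffold_binding	family_local
dmel_4E-HP	46	N	scaffold_binding	family_local
dmel_4E-HP	82	Q	scaffold_binding	family_local
dmel_4E-HP	139	E	scaffold_binding	family_local
dmel_4E-HP	140	N	scaffold_binding	family_local
dmel_4E-HP	143	M	scaffold_binding	family_local
dmel_4E-HP	68	Y	cap	family_local
dmel_4E-HP	102	E	cap	family_local
dmel_4E-HP	124	Q	cap	family_local
dmel_4E-HP	164	K	cap	family_local
dmel_4E-HP	166	P	cap	family_local
dmel_4E-HP	169	S	cap	family_local
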