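res_name	rotamer_id	chi1	chi2	chi3	chi4	probability
LEU	1	-60	180			0.25
LEU	2	180	180			0.25
LEU	3	65	180			0.25
LEU	4	-60	-179			0.25
SER	1	-60				0.5
SER	2	180				0.5
VAL	1	-60				0.3333
VAL	2	180				0.3333
VAL	3	65				0.3333
TYR	1	-60	180			0.3333
TYR	2	180	180			0.3333
TYR	3	65	180			0.3333
LYS	1	-60	180	180	175	0.3333
LYS	2	180	180	180	175	0.3333
LYS	3	65	180	180	175	0.3333
MET	1	-60	180	180		0.3333
MET	2	180	180	180		0.3333
MET	3	65	180	180		0.3333
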