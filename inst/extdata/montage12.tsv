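channel	x_mm	y_mm	z_mm	reference
F3	-2.0	5.0	NA	FALSE
F4	2.0	5.0	NA	FALSE
C3	-3.2	2.2	NA	FALSE
C4	3.2	2.2	NA	FALSE
P3	-2.5	-3.8	NA	FALSE
P4	2.5	-3.8	NA	FALSE
P5	-4.5	-4.5	NA	FALSE
P6	4.5	-4.5	NA	FALSE
T3	-7.2	-3.6	NA	FALSE
T4	7.2	-3.6	NA	FALSE
T5	-5.8	-8.3	NA	FALSE
T6	5.8	-8.3	NA	FALSE
Ref	0.0	9.0	NA	TRUE
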