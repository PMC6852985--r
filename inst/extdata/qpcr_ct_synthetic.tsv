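sample	genotype	assay	ct
s1	sexual	miR8175	23.00
s1	sexual	miR8175	23.12
s1	sexual	miR8175	22.95
s1	sexual	actin	20.11
s1	sexual	actin	20.04
s1	sexual	actin	20.18
s2	sexual	miR8175	23.25
s2	sexual	miR8175	23.08
s2	sexual	miR8175	23.19
s2	sexual	actin	20.22
s2	sexual	actin	20.09
s2	sexual	actin	20.15
s3	sexual	miR8175	22.88
s3	sexual	miR8175	23.01
s3	sexual	miR8175	22.93
s3	sexual	actin	19.95
s3	sexual	actin	20.07
s3	sexual	actin	20.02
s4	apomictic	miR8175	26.12
s4	apomictic	miR8175	26.25
s4	apomictic	miR8175	26.04
s4	apomictic	actin	20.01
s4	apomictic	actin	20.12
s4	apomictic	actin	19.96
s5	apomictic	miR8175	26.41
s5	apomictic	miR8175	26.30
s5	apomictic	miR8175	26.34
s5	apomictic	actin	20.18
s5	apomictic	actin	20.25
s5	apomictic	actin	20.11
s6	apomictic	miR8175	25.99
s6	apomictic	miR8175	26.11
s6	apomictic	miR8175	26.05
s6	apomictic	actin	19.92
s6	apomictic	actin	20.05
s6	apomictic	actin	19.98
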