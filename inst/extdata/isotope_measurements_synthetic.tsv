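sample_id	timepoint_days	treatment	delta_fum	c_fum	delta_nfum	c_nfum
D_13C_r1	32	13C	21.4	42.1	-26.8	18.3
D_13C_r2	32	13C	18.9	39.6	-27.1	17.2
D_13C_r3	32	13C	24.2	44.8	-26.2	19.0
D_12C_r1	32	12C	-27.6	41.3	-26.9	18.1
D_12C_r2	32	12C	-28.4	40.2	-27.3	17.6
D_12C_r3	32	12C	-27.1	43.0	-26.5	18.8
D_13C_r1	18	13C	-8.1	40.8	-26.6	17.9
D_13C_r2	18	13C	-10.4	41.5	-27.0	18.4
D_13C_r3	18	13C	-6.9	39.9	-26.4	17.5
D_12C_r1	18	12C	-27.0	40.6	-26.8	18.0
D_12C_r2	18	12C	-26.6	42.2	-27.2	18.6
D_12C_r3	18	12C	-27.9	41.0	-26.3	17.7
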