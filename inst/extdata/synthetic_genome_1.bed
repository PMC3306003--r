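synthg1	3004	3292	.	0	.
synthg1	5760	6015	.	0	.
synthg1	8542	8902	.	0	.
synthg1	9413	9704	.	0	.
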