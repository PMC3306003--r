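synthg2	3008	3263	.	0	.
synthg2	4511	4727	.	0	.
synthg2	6813	6954	.	0	.
synthg2	7178	7436	.	0	.
synthg2	8302	8467	.	0	.
synthg2	8511	8685	.	0	.
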