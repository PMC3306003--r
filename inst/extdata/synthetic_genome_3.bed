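synthg3	869	1118	.	0	.
synthg3	2554	2740	.	0	.
synthg3	3622	3916	.	0	.
synthg3	4055	4403	.	0	.
synthg3	6168	6417	.	0	.
synthg3	6898	7129	.	0	.
synthg3	8365	8521	.	0	.
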