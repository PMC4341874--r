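# organism: Pseudomonas aeruginosa
# agent: piperacillin-tazobactam
# source: synthetic EUCAST-style snapshot (constructed 2026-09-25 from the published shape of the EUCAST wild-type distribution: mode 4 mg/L, wild type <= 16 mg/L, ~15% resistant tail); not a retrieval of the live EUCAST database
mic_mg_L	freq
0.5	0.005
1	0.025
2	0.12
4	0.30
8	0.22
16	0.11
32	0.07
64	0.055
128	0.045
256	0.03
512	0.02
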