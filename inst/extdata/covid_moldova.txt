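2.0167
2.2917
2.1395
1.4134
2.6539
2.4832
2.5873
2.5588
2.0058
2.4013
2.6438
1.6959
1.9305
2.0351
1.1280
0.2486
2.3525
2.2042
2.4167
2.2600
2.1084
2.1898
1.4898
1.8222
2.1382
1.9901
2.0681
2.1443
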