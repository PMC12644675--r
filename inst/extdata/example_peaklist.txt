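m/z	intensity
1232.12	310
1540.14	1250
1848.55	2200
1848.75	9800
1848.95	2400
1849.15	500
2464.03	150
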