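# synthetic two-year accident-loss series (S = D*A*L); previous-year factor rates +9.7/+12.0/-18.9%
year,D,A,L,S
1992,700000000000,0.000000800,9500000,5320000000000
1997,767900000000,0.000000896,7704500,5300991852800
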