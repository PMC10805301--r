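# Synthetic stand-in list of subacute-manageable intervention codes
# (CCI-style strings; the consensus registry itself is site configuration).
1.AN.09
1.SZ.35
2.GY.70
2.OD.71
3.IP.10
1.YV.55
2.ZZ.02
1.WL.03
3.AN.40
1.JE.50
2.HZ.13
1.OT.52
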