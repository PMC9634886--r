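1146.927450 0.160109
1147.128022 0.496972
1147.328483 0.83647
1147.528878 1
1147.729231 0.944595
1147.929553 0.746016
1148.129854 0.510063
1148.330139 0.309071
1148.530413 0.168792
1148.730680 0.0841354
1148.930941 0.0386535
1149.131199 0.0164957
1149.331456 0.00658093
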