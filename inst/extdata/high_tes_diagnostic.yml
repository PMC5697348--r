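# High-Tes producer line with the diagnostic sensor variant.
# Keys not listed here are filled from the shipped reference set.
V_tes: 110 mg/l/OD/min
Ki_I: 0.1
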