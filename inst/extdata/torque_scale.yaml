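q1: 2.0
q2: 2.0
q3: 1.5
q4: 1.0
q5: 0.3
q6: 0.2
q7: 0.15
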