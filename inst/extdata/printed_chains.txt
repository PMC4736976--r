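# 16-symbol SHCC chains of the worked examples, one per line:
# 1: subject template chain
# 2: P300 candidate chain (distance to template 0.55)
# 3: non-P300 candidate chain (distance to template 0.92)
# 4: discretized ERP chain (tortuosity 0.64)
0.05 -0.02 -0.05 0.08 0.07 -0.01 0.01 -0.03 0.04 -0.04 -0.09 0.01 0.05 -0.03 -0.04 0.04
-0.01 -0.04 -0.05 0.04 0.05 0.05 0.02 -0.05 -0.02 -0.05 -0.02 0.05 0.02 0 -0.01 -0.01
0.07 -0.03 0 -0.03 0.06 0.04 -0.10 0.06 0.01 -0.04 -0.04 0.06 -0.09 0.01 0.11 0.05
0.06 -0.02 -0.06 0.06 0.05 0.02 0.01 -0.04 0.04 -0.03 -0.09 0.04 0.05 -0.01 -0.02 0.04
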