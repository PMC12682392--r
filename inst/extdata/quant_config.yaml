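# Default acquisition schedule for the quantification stage.
offsets_ppm: [-4.3, -3.5, -2.7, 2.7, 3.5, 4.3]
echo_times: [0.002, 0.003, 0.004]   # seconds
b_values: [0, 800]                  # s/mm^2
field_mhz: 127.728                  # 3 T proton frequency
alpha_normality: 0.05
p_enter: 0.05
p_remove: 0.10
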