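# Frozen calibrated initial state for the scenario analyses.
# Chosen once by a grid scan so that the full model cycles and the
# no-viability-selection variant crashes at generation 10; see the
# methods vignette for the calibration procedure.
"X": [94.0, 94.0, 94.0]
"Y": [94.0, 94.0, 94.0]
b_mean_X: 0.36
b_mean_Y: 0.36
p_mean_X: 0.36
p_mean_Y: 0.36
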