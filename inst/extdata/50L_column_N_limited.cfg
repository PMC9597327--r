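name: 50L_column_N_limited
geometry: bubble_column
incident_intensity_Io: 360
radius_R: 0.095000000000000001
photoperiod_light_h: 16
volume: 50
nitrogen_N0: 61.600000000000001
medium_description: 5 x f/2
initial_X: 14.847809948032664
initial_Q: 0.12
duration: 14
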