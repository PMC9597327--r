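name: 5L_flat_panel_4xf2
geometry: flat_panel
incident_intensity_Io: 350
path_length_L: 0.050000000000000003
photoperiod_light_h: 12
volume: 5
nitrogen_N0: 49.280000000000001
medium_description: 4 x f/2
initial_X: 9.2798812175204155
initial_Q: 0.12
duration: 16
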