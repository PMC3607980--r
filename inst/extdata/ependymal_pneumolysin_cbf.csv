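time_min,ciliafa_hz,direct_obs1_hz,direct_obs2_hz,direct_obs1_second_hz
0,43.05,39.06,42.37,47.17
0,42.55,37.87,41.67,40.32
0,45.25,43.85,44.64,44.64
0,42.40,39.68,41.67,39.68
0,43.07,41.66,42.37,41.67
0,43.31,38.46,40.98,46.29
0,39.80,33.78,37.88,39.68
0,40.30,30.86,32.00,30.86
5,18.86,18.79,18.79,18.25
5,24.28,23.36,23.15,23.15
5,20.78,21.32,22.52,24.75
5,18.97,18.79,18.66,18.66
5,18.71,18.79,18.51,18.94
5,18.82,18.79,18.66,18.51
5,20.77,22.12,23.15,22.52
5,30.43,32.00,30.86,30.86
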