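dose_gy,r2_s1,sd_r2,n_voxels
0,1.65,0.3,200
1.7,9.785,0.3,200
3.4,17.92,0.3,200
5.1,26.055,0.3,200
6.8,34.19,0.3,200
8.5,42.325,0.3,200
10.2,50.46,0.3,200
11.9,58.595,0.3,200
13.6,66.73,0.3,200
15.3,74.865,0.3,200
17,83,0.3,200
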