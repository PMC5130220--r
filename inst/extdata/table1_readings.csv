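t_s,f_red_khz,f_green_khz,f_blue_khz,voltage_v
7200,2.6483,3.2657,2.7727,3.0
7205.5,3.0148,3.9876,4.4974,3.0
7211,2.8477,3.7075,4.0711,3.0
7216.5,2.7722,3.5482,3.8479,3.0
7222,2.6774,3.3041,3.5226,3.0
7227.5,2.5312,2.8258,2.9179,3.0
7233,2.3521,1.9657,1.8391,3.0
7238.5,2.1432,1.2072,1.4065,3.0
7244,1.8243,0.7237,0.6862,3.0
7249.5,1.7325,0.6087,0.5918,3.0
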