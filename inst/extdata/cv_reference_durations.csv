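syllable,c_frames,v_frames,cv_frames
fi,9,5.65,14.65
fa,8.175,6.475,14.65
fu,7.525,6.9,14.425
pi,6.55,7.275,13.825
pa,7.475,8.55,16.025
pu,6.6,7.625,14.225
si,8.775,5.875,14.65
sa,8.9,6.05,14.95
su,9.025,5.2,14.225
ti,7.6,6.825,14.425
ta,6.85,6.7,13.55
tu,7.025,4.85,11.875
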