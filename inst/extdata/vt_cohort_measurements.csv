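speaker,length_mm,height_mm,width_mm
SP1,97,92,40
SP2,77,76,32
SP3,99,81,40
SP4,89,69,34
SP5,94,86,36
SP6,87,81,32
SP7,88,90,38
SP8,87,67,34
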