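# microRNAs previously reported as biomarkers of metastatic prostate cancer
miR-145-5p
miR-101-3p
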