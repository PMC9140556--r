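m1,m2,m3,m4,m5,m6
277,437,437,596,757,2230
277,363,405,522,535,613
213,298,821,1300,1601,1620
5,149,618,1034,2441,2640
437,565,714,927,1119,4462
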