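label,count,area_um2
10-500,34,5897.6
501-1000,12,7938.6
1001-2000,14,20291.5
2001-4000,22,64989
4001-6000,18,84622.5
6001-8000,15,104020.6
8001-10000,7,59847.7
10001-,13,182616.7
Total,135,530224.3
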