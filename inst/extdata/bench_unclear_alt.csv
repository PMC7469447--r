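label,count,area_um2
50-500,45,8766.6
501-1000,19,13715.2
1001-2000,31,45496.1
2001-4000,36,103826.7
4001-6000,24,121763.6
6001-8000,15,105405.8
8001-10000,4,33830.9
10001-,5,58116.4
Total,179,490921.3
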