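label,count,area_um2
50-500,34,7341.6
501-1000,13,9349.9
1001-2000,20,29427.6
2001-4000,27,76285.2
4001-6000,16,87302.8
6001-8000,10,67072.4
8001-10000,3,26700.0
10001-,9,171738.2
Total,133,475217.7
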