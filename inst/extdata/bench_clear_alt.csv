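label,count,area_um2
10-500,36,7577.2
501-1000,14,9496.3
1001-2000,16,22828.2
2001-4000,24,70088.1
4001-6000,20,96894.5
6001-8000,16,110982.7
8001-10000,8,69011.4
10001-,10,131721.0
Total,144,518599.5
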