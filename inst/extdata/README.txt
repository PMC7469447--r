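Benchmark comparison tables: per-size-bin cell counts and summed areas
(square microns) for two adipose-tissue sections, each analysed with a
reference tool (*_ref) and with a contour-based counter after manual
border correction (*_alt). "clear" = section with well-defined cell
membranes, "unclear" = section with faint/broken membranes. The Total
row is kept as printed by the original analyses (in bench_unclear_ref
the printed total count, 133, exceeds the bin sum by one; the file
preserves both as published).
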