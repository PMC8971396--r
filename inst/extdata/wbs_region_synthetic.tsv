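symbol	chrom	start	end	score
POM121	chr7	72750000	72780000	NA
NSUN5	chr7	72805000	72835000	NA
TRIM50	chr7	72860000	72890000	NA
FKBP6	chr7	72915000	72945000	1
FZD9	chr7	72970000	73000000	2
BAZ1B	chr7	73025000	73055000	3
BCL7B	chr7	73080000	73110000	1
TBL2	chr7	73135000	73165000	1
MLXIPL	chr7	73190000	73220000	2
VPS37D	chr7	73245000	73275000	NA
DNAJC30	chr7	73300000	73330000	NA
BUD23	chr7	73355000	73385000	NA
STX1A	chr7	73410000	73440000	3
ABHD11	chr7	73465000	73495000	NA
CLDN3	chr7	73520000	73550000	NA
CLDN4	chr7	73575000	73605000	NA
METTL27	chr7	73630000	73660000	NA
ELN	chr7	73685000	73715000	1
LIMK1	chr7	73740000	73770000	3
EIF4H	chr7	73795000	73825000	3
LAT2	chr7	73850000	73880000	1
RFC2	chr7	73905000	73935000	2
CLIP2	chr7	73960000	73990000	3
GTF2IRD1	chr7	74015000	74045000	2
GTF2I	chr7	74070000	74100000	4
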