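symbol	chrom	start	end	score	segment
DGCR6	chr22	18950000	18978000	NA	A-B
PRODH	chr22	18995000	19023000	2	A-B
DGCR2	chr22	19040000	19068000	1	A-B
DGCR14	chr22	19085000	19113000	NA	A-B
TSSK2	chr22	19130000	19158000	NA	A-B
GSC2	chr22	19175000	19203000	NA	A-B
SLC25A1	chr22	19220000	19248000	2	A-B
CLTCL1	chr22	19265000	19293000	1	A-B
HIRA	chr22	19310000	19338000	3	A-B
MRPL40	chr22	19355000	19383000	NA	A-B
C22orf39	chr22	19400000	19428000	NA	A-B
UFD1	chr22	19445000	19473000	2	A-B
CDC45	chr22	19490000	19518000	1	A-B
CLDN5	chr22	19535000	19563000	1	A-B
SEPTIN5	chr22	19580000	19608000	1	A-B
GP1BB	chr22	19625000	19653000	NA	A-B
TBX1	chr22	19670000	19698000	3	A-B
GNB1L	chr22	19715000	19743000	2	A-B
TXNRD2	chr22	19760000	19788000	1	A-B
COMT	chr22	19805000	19833000	2	A-B
ARVCF	chr22	19850000	19878000	1	A-B
TANGO2	chr22	19895000	19923000	1	A-B
MIR185HG	chr22	19940000	19968000	NA	A-B
DGCR8	chr22	19985000	20013000	4	A-B
TRMT2A	chr22	20030000	20058000	NA	A-B
RANBP1	chr22	20075000	20103000	2	A-B
ZDHHC8	chr22	20120000	20148000	2	A-B
RTN4R	chr22	20165000	20193000	1	A-B
DGCR6L	chr22	20210000	20238000	NA	A-B
USP41	chr22	20255000	20283000	NA	A-B
ZNF74	chr22	20300000	20328000	1	B-D
SCARF2	chr22	20345000	20373000	1	B-D
KLHL22	chr22	20390000	20418000	2	B-D
MED15	chr22	20435000	20463000	2	B-D
POM121L4P	chr22	20480000	20508000	NA	B-D
TMEM191A	chr22	20525000	20553000	NA	B-D
PI4KA	chr22	20570000	20598000	3	B-D
SERPIND1	chr22	20615000	20643000	NA	B-D
SNAP29	chr22	20660000	20688000	2	B-D
CRKL	chr22	20705000	20733000	3	B-D
AIFM3	chr22	20750000	20778000	1	B-D
LZTR1	chr22	20795000	20823000	2	B-D
THAP7	chr22	20840000	20868000	1	B-D
P2RX6	chr22	20885000	20913000	NA	B-D
SLC7A4	chr22	20930000	20958000	1	B-D
LRRC74B	chr22	20975000	21003000	NA	B-D
POM121L8P	chr22	21020000	21048000	NA	B-D
RIMBP3	chr22	21065000	21093000	NA	B-D
HIC2	chr22	21110000	21138000	2	D-F
TMEM191C	chr22	21155000	21183000	NA	D-F
PI4KAP2	chr22	21200000	21228000	NA	D-F
RIMBP3B	chr22	21245000	21273000	NA	D-F
RIMBP3C	chr22	21290000	21318000	NA	D-F
UBE2L3	chr22	21335000	21363000	3	D-F
YDJC	chr22	21380000	21408000	NA	D-F
CCDC116	chr22	21425000	21453000	NA	D-F
SDF2L1	chr22	21470000	21498000	1	D-F
PPIL2	chr22	21515000	21543000	1	D-F
YPEL1	chr22	21560000	21588000	2	D-F
MAPK1	chr22	21605000	21633000	4	D-F
PPM1F	chr22	21650000	21678000	2	D-F
TOP3B	chr22	21695000	21723000	3	D-F
VPREB1	chr22	21740000	21768000	NA	D-F
ZNF280B	chr22	21785000	21813000	NA	D-F
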