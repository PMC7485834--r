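locus_name	chrom	start	end	trait
ABCA1	9	107543283	107690527	HDL
APOA4-APOC3-APOA1	11	116660086	116717358	HDL
APOE-APOC1-APOC4-APOC2	19	45409039	45452822	HDL
CETP	16	56995762	57017757	HDL
LCAT	16	67973788	67978015	HDL
LIPC	15	58702768	58861073	HDL
LIPG	18	47088627	47119769	HDL
PLTP	20	44527404	44541218	HDL
SCARB1	12	125262177	125348329	HDL
APOB	2	21224301	21266945	LDL
HMGCR	5	74632154	74657929	LDL
LDLR	19	11200038	11244506	LDL
LPA	6	160952515	161087407	LDL
MYLIP	6	16129086	16148479	LDL
NPC1L1	7	44552134	44580914	LDL
PCSK9	1	55505221	55530525	LDL
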