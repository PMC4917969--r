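chr1	150547027	150552066	MCL1
chr1	204485511	204527248	MDM4
chr5	1253282	1295184	TERT
chr7	55086714	55324313	EGFR
chr7	92234235	92465908	CDK6
chr8	38268656	38326352	FGFR1
chr8	128748315	128753680	MYC
chr10	89623195	89728532	PTEN
chr11	69455855	69469242	CCND1
chr12	58141510	58149796	CDK4
chr12	69201956	69239214	MDM2
chr13	48877887	49056026	RB1
chr17	7565097	7590856	TP53
chr17	37844393	37884915	ERBB2
chr19	30302805	30315215	CCNE1
chr21	39751949	40033704	ERG
chr21	42836478	42903043	TMPRSS2
chrX	66764465	66950461	AR
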