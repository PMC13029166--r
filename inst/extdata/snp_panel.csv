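snp_id,gene,chromosome,pathway,allele_a,allele_b,counted_allele,maf_global,maf_mxl,maf_cohort,pheno_specific,note
rs1532624,CETP,16,RCT,C,A,A,0.31,0.35,0.39,,
rs289714,CETP,16,RCT,T,C,C,0.29,0.24,0.35,,
rs5882,CETP,16,RCT,A,G,G,0.37,0.44,0.44,,
rs4149310,ABCA1,9,RCT,G,A,A,0.46,0.35,0.38,TG,
rs9282541,ABCA1,9,RCT,C,T,T,0.01,0.07,0.10,HDL,
rs805743,LOC,20,RCT,T,C,C,0.35,0.33,0.30,,intergenic locus from Mexican GWAS
rs10889337,ANGPTL3,1,CLU,G,A,A,0.41,0.34,0.43,,
rs1044250,ANGPTL4,19,CLU,C,T,T,0.31,0.40,0.40,,
rs2278236,ANGPTL4,19,CLU,A,C,C,0.49,0.49,0.48,,
rs7255436,ANGPTL4,19,CLU,C,A,A,0.49,0.49,0.49,,
rs1527483,CD36,7,CLU,C,T,T,0.10,0.08,0.12,,
rs10499859,CD36,7,CLU,A,G,G,0.35,0.50,0.48,,
rs12678919,LPL,8,CLU,A,G,G,0.05,0.05,0.05,,
rs1260326,GCKR,2,LPF,C,T,T,0.38,0.35,0.31,,
rs1800588,LIPC,15,LPF,C,T,T,0.29,0.49,0.41,,
rs2286276,MLXIPL,7,LPF,C,G,G,0.27,0.35,0.40,,also cited as rs2886276
rs1801282,PPARG,3,LPF,C,G,G,0.11,0.13,0.12,,
rs12639162,PPARG,3,LPF,A,G,G,0.43,0.49,0.46,,
rs3173798,CD36,7,CLU,T,C,C,NA,NA,0.13,,reported HWE-fail; synthetic MAF placeholder
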