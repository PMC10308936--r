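locus_tag,protein_name,rank_mean_wo_n,rank_sd_wo_n,rank_mean_w_n,rank_sd_w_n,psm_m1_wo_n,psm_m2_wo_n,psm_m1_w_n,psm_m2_w_n,conf_m1_wo_n,conf_m2_wo_n,conf_m1_w_n,conf_m2_w_n
PVLB_23220,PrkA family serine protein kinase,1653,21.2,,,1,3,1,,H,H,H,ND
PVLB_16155,Potassium-transporting ATPase subunit B,222.5,29,,,2,1,,,H,H,ND,ND
PVLB_21235,OmpA family outer membrane protein,1568.5,37.5,,,2,1,,,H,H,ND,ND
PVLB_04415,"Ubiquinol-cytochrome c reductase, cytochrome c1",1361.5,48.8,,,2,2,,,H,H,ND,ND
PVLB_01645,Malate dehydrogenase,1468.5,81.3,,,2,3,,1,H,H,ND,H
PVLB_02140,Poly(hydroxyalkanoate) granule-associated protein,1487,101.8,,,3,1,,,H,H,ND,ND
PVLB_01155,LytTR family two component transcriptional regulator,1732.5,102.5,,,1,1,,1,H,H,ND,H
PVLB_02145,PhaF protein,673.5,159.1,,,4,6,,,H,H,ND,ND
PVLB_23550,Pyruvate dehydrogenase subunit E1,969,162.6,,,5,6,,1,H,H,ND,M
PVLB_23795,Glycine betaine/L-proline ABC transporter periplasmic binding protein,847,251.7,,,4,8,,,H,H,ND,ND
PVLB_08345,Transcriptional regulator CysB,1386.5,344.4,,,3,3,,,H,H,ND,ND
PVLB_21320,Lipoprotein,670.5,372.6,,,1,4,,,H,H,ND,ND
PVLB_05585,OmpA/MotB domain-containing protein,1668,400.2,,,1,2,,,H,H,ND,ND
PVLB_06300,Extracellular solute-binding protein,874.5,425,,,2,11,,1,H,H,ND,H
PVLB_02735,HflK protein,1158.5,221.3,,,4,6,,1,H,H,ND,H
PVLB_05670,Leucine ABC transporter subunit substrate-binding protein LivK,394,60.8,948,116,11,14,6,6,H,H,H,H
PVLB_05350,Extracellular solute-binding protein,798.5,195.9,,,3,6,1,1,H,H,H,H
PVLB_15240,"Transcriptional regulator MvaT, P16 subunit",1063,60.8,,,3,3,1,,H,H,H,ND
PVLB_01935,Glutamine synthetase,422,93.3,1100.5,71.4,8,10,3,3,H,H,H,H
PVLB_20160,Arginine deiminase,629.5,33.2,1359,121.6,9,11,3,3,H,H,H,H
PVLB_25325,Pyruvate carboxylase subunit B,373,8.5,1177.5,57.3,14,11,2,2,H,H,H,H
PVLB_24595,Putrescine ABC transporter periplasmic putrescine-binding protein,468.5,88.4,1283.5,58.7,9,9,2,3,H,H,H,H
PVLB_24275,LysM domain/BON superfamily protein,1039,83.4,,,2,3,,2,H,H,ND,H
PVLB_23145,Extracellular solute-binding protein,651.5,62.9,,,7,7,1,1,H,H,H,H
PVLB_02885,Extracellular ligand-binding receptor,765,314,1854,178.2,3,6,2,1,H,H,H,H
PVLB_25330,Pyruvate carboxylase subunit A,547,90.5,1643.5,253.9,9,10,1,3,H,H,H,H
PVLB_16295,2-oxoglutarate dehydrogenase E1 component,915,42.4,,,6,3,,2,H,H,ND,H
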