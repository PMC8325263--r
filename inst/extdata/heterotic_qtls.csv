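trait,qtl,chrom,interval,dataset,lod,a_star,d_star,da,r2_pct,gene_mode
LL,qLL4a,4,InDel70-umc1142,Z1,2.9,4.1,NA,NA,7.6,PD
LL,qLL7a,7,umc1015-umc1713,Z1,4.7,-5.1,NA,NA,11.6,PD
LL,qLL7b,7,umc1015-umc1713,Z3,2.8,NA,NA,-9.7,10.5,PD
LW,qLW2a,2,bnlg1327-bnlg2277,Z1,3.1,0.4,NA,NA,7.1,PD
LW,qLW4a,4,InDel68-S4_69842356,Z1,4.2,0.5,NA,NA,10.4,PD
LW,qLW7a,7,umc1412-InDel107,Z1,3.0,0.4,NA,NA,8.3,D
LW,qLW7b,7,umc2160-umc1159,Z1,3.1,-0.4,NA,NA,7.2,A
LW,qLW9a,9,umc1586-S9_24472332,Z1,2.6,0.5,NA,NA,10.2,A
LA,qLA4a,4,InDel68-S4_69842356,Z1,10.7,1.4,NA,NA,20.5,A
LA,qLA4b,4,umc2061-umc1969,Z1,3.7,-0.7,NA,NA,6.1,A
LA,qLA7a,7,umc2160-umc1159,Z1,3.1,-0.7,NA,NA,5.1,PD
LA,qLA9a,9,umc1271-asg63a,Z1,2.6,0.6,NA,NA,4.1,PD
LA,qLA10a,10,bnlg1712-phi050,Z1,5.8,0.9,NA,NA,9.7,PD
LA,qLA4c,4,umc1164-bx4,Z3,3.3,NA,NA,1.9,11.4,D
SDW,qSDW4a,4,npi270-php20071,Z1,2.9,-0.1,NA,NA,8.4,PD
SDW,qSDW7a,7,S7_21278179-umc1978,Z1,3.9,-0.1,NA,NA,11.5,PD
SDW,qSDW5a,5,ufg49-umc1315,Z2,2.7,NA,0.2,NA,8.1,D
SDW,qSDW10a,10,umc2122-umc1993,Z2,2.8,NA,0.2,NA,10.1,OD
SDW,qSDW4b,4,PAV5-umc1669,Z3,3.3,NA,NA,0.5,12.0,OD
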