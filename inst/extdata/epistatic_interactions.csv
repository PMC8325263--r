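trait,dataset,chrom_i,interval_i,chrom_j,interval_j,lod,a_i,a_j,aa_ij,r2_pct
LL,H3,3,npi425a-npi420,4,umc2139-umc52,5.3,-1.6,-0.3,-6.9,10.1
LL,H3,2,umc2030-umc1259,4,psr144b-umc1943,5.2,-2.0,-1.7,-7.0,9.6
LL,H3,4,agrr301-bnlg490,5,S5_212169465-InDel90,5.5,-2.9,1.6,-7.0,9.6
LL,H3,4,phi295450-InDel63,8,umc1913-csu329,5.9,-2.3,-0.4,7.3,13.2
LL,H3,4,InDel78-S4_240467004,9,mmp131-asg44,5.3,-1.8,-0.7,6.5,9.7
LL,Z3,8,mmp166-npi585a,9,umc1691-umc1271,5.2,2.8,5.8,-12.6,10.1
LL,Z3,9,umc1570-lim99b,9,isu111b-csu471,5.3,6.7,-1.1,13.1,9.4
LW,H3,2,umc2030-umc1259,2,npi287a-umc44b,5.8,0.1,0.1,0.7,9.8
LW,H3,5,mmp169-php20566,5,S5_1531780-PAV58,5.0,0.0,0.0,-0.6,8.4
LW,H3,3,npi420-InDel62,10,asg19b-csu48,5.2,0.2,0.0,0.8,14.0
LW,Z3,3,mmc0022-InDel58,3,npi420-InDel62,6.0,1.1,-0.7,1.8,19.7
LA,H3,1,umc1177-tub1,6,rz143a-umc85a,5.2,0.3,0.3,-1.1,17.3
LA,Z3,5,S5_1531780-PAV58,8,umc1316-bnl12.30a,5.1,1.0,0.7,-2.2,18.3
SDW,H3,1,lim122-cdo1387b,6,umc85a-isu085a,5.1,0.0,0.0,-0.2,18.6
SDW,Z3,1,asg30b-umc1169,8,cdo460-mmp57,5.5,-0.1,0.1,0.4,9.4
SDW,Z3,4,PAV42-PAV59,4,PAV93-PAV30,6.3,0.4,0.4,-0.6,23.6
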