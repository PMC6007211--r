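name	ncbi_gene_id
shp2	5781
ptpn11	5781
gpc5	2262
galnt2	2590
igf1r	3480
brf2	55290
trim32	22954
fkbp51	2289
fkbp5	2289
pten	5728
tp	1890
tymp	1890
pdecgf	1890
foxd3	27022
gcs	7357
ugcg	7357
lef1	51176
egfr	1956
c1galt1	56913
nampt	10135
erbb2	2064
her-2	2064
tp53	7157
p53	7157
kras	3845
myc	4609
vegfa	7422
vegf	7422
cdh1	999
e-cadherin	999
ccnd1	595
cyclin d1	595
bcl2	596
bcl-2	596
mmp9	4318
mmp-9	4318
cdkn2a	1029
stat3	6774
akt1	207
esr1	2099
b4galt1	2683
st6gal1	6480
mgat5	4249
fut8	2530
afp	174
survivin	332
birc5	332
timp1	7076
timp-1	7076
cea	1048
ceacam5	1048
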