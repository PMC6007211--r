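name	doid
oral squamous cell carcinoma	DOID:0050866
oscc	DOID:0050866
squamous cell carcinoma	DOID:1749
lung cancer	DOID:1324
lung carcinoma	DOID:3905
non-small cell lung carcinoma	DOID:3908
non-small cell lung cancer	DOID:3908
nsclc	DOID:3908
lung adenocarcinoma	DOID:3910
pancreatic cancer	DOID:1793
breast cancer	DOID:1612
breast carcinoma	DOID:3459
colorectal cancer	DOID:9256
colorectal carcinoma	DOID:9256
colon cancer	DOID:219
colon carcinoma	DOID:219
gastric cancer	DOID:10534
stomach cancer	DOID:10534
gastric carcinoma	DOID:10534
ovarian cancer	DOID:2394
ovarian carcinoma	DOID:2394
prostate cancer	DOID:10283
hepatocellular carcinoma	DOID:684
hcc	DOID:684
liver cancer	DOID:3571
melanoma	DOID:1909
leukemia	DOID:1240
chronic lymphocytic leukemia	DOID:1040
cll	DOID:1040
glioma	DOID:3070
gliomas	DOID:3070
high grade glioma	DOID:3070
hgg	DOID:3070
glioblastoma	DOID:3068
bladder cancer	DOID:11054
bladder carcinoma	DOID:11054
bladder urothelial carcinoma	DOID:4006
urothelial carcinoma	DOID:4006
esophageal cancer	DOID:5041
adrenocortical tumor	DOID:3948
adrenocortical carcinoma	DOID:3948
thyroid cancer	DOID:1781
papillary thyroid carcinoma	DOID:3969
renal cell carcinoma	DOID:4450
cervical cancer	DOID:4362
endometrial cancer	DOID:1380
osteosarcoma	DOID:3347
hepatitis b	DOID:2043
chronic hepatitis b	DOID:2043
diabetes mellitus	DOID:9351
myocardial infarction	DOID:5844
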