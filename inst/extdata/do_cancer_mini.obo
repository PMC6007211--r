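format-version: 1.2
ontology: doid-cancer-mini
remark: Hand-assembled miniature excerpt of the Disease Ontology cancer
remark: subtree (root DOID:162) plus non-cancer decoy branches, for offline
remark: testing of the cancer relevance filter. Identifiers are real DOIDs;
remark: the term set and cross-links are heavily down-sampled.

[Term]
id: DOID:4
name: disease

[Term]
id: DOID:14566
name: disease of cellular proliferation
is_a: DOID:4 ! disease

[Term]
id: DOID:162
name: cancer
is_a: DOID:14566 ! disease of cellular proliferation

[Term]
id: DOID:305
name: carcinoma
is_a: DOID:162 ! cancer

[Term]
id: DOID:1749
name: squamous cell carcinoma
is_a: DOID:305 ! carcinoma

[Term]
id: DOID:0050866
name: oral squamous cell carcinoma
is_a: DOID:1749 ! squamous cell carcinoma

[Term]
id: DOID:1324
name: lung cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:3905
name: lung carcinoma
is_a: DOID:1324 ! lung cancer

[Term]
id: DOID:3908
name: lung non-small cell carcinoma
is_a: DOID:3905 ! lung carcinoma

[Term]
id: DOID:3910
name: lung adenocarcinoma
is_a: DOID:3905 ! lung carcinoma

[Term]
id: DOID:1793
name: pancreatic cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:1612
name: breast cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:3459
name: breast carcinoma
is_a: DOID:1612 ! breast cancer

[Term]
id: DOID:9256
name: colorectal cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:219
name: colon cancer
is_a: DOID:9256 ! colorectal cancer

[Term]
id: DOID:10534
name: stomach cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:2394
name: ovarian cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:10283
name: prostate cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:684
name: hepatocellular carcinoma
is_a: DOID:3571 ! liver cancer

[Term]
id: DOID:3571
name: liver cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:1909
name: melanoma
is_a: DOID:162 ! cancer

[Term]
id: DOID:1240
name: leukemia
is_a: DOID:162 ! cancer

[Term]
id: DOID:1040
name: chronic lymphocytic leukemia
is_a: DOID:1240 ! leukemia

[Term]
id: DOID:3070
name: malignant glioma
is_a: DOID:162 ! cancer

[Term]
id: DOID:3068
name: glioblastoma
is_a: DOID:3070 ! malignant glioma

[Term]
id: DOID:11054
name: urinary bladder cancer
is_a: DOID:162 ! cancer

[Term]
id: DOID:4006
name: bladder urothelial carcinoma
is_a: DOID:11054 ! urinary bladder cancer

[Term]
id: DOID:3948
name: adrenocortical carcinoma
is_a: DOID:162 ! cancer

[Term]
id: DOID:3347
name: osteosarcoma
is_a: DOID:162 ! cancer

[Term]
id: DOID:934
name: viral infectious disease
is_a: DOID:4 ! disease

[Term]
id: DOID:2043
name: hepatitis B
is_a: DOID:934 ! viral infectious disease

[Term]
id: DOID:9351
name: diabetes mellitus
is_a: DOID:4 ! disease

[Term]
id: DOID:5844
name: myocardial infarction
is_a: DOID:4 ! disease
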