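condition	siu_percent	incidence
HIV	6.17	1.53e-04
Cancer	5.19	5.37e-03
Diabetes mellitus	4.42	6.13e-03
Herpes simplex	2.34	2.50e-03
Arthritis	1.30	4.10e-04
Atrial fibrillation	1.08	6.45e-02
Gastroparesis	1.05	2.50e-05
Heart failure	0.970	1.77e-04
Schizophrenia	0.944	7.00e-04
Crohn's disease	0.838	7.90e-05
Dementia	0.769	1.51e-03
Alzheimer's disease	0.753	1.26e-03
Amyotrophic lateral sclerosis	0.604	1.81e-05
Parkinson's disease	0.562	1.77e-04
Breast cancer	0.504	7.51e-04
Colitis	0.440	8.80e-05
Asthma	0.419	7.00e-04
Epilepsy	0.392	4.70e-04
Lyme disease	0.345	7.00e-05
Hepatitis C	0.308	5.48e-05
Spina bifida	0.265	3.49e-04
Leukemia	0.255	1.69e-04
Hypothyroidism	0.233	2.86e-04
Chronic pancreatitis	0.228	4.35e-05
Celiac disease	0.217	6.50e-05
Cardiomyopathy	0.196	5.00e-05
Multiple myeloma	0.159	7.76e-05
Lymphoma	0.148	2.58e-04
Brain tumor	0.122	7.54e-05
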