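disease,columbia_count,columbia_percent,stanford_count,stanford_percent,n_genes,cluster_name
Alcoholism,27638,2.82,11363,4.10,81,adulthood
Allergic rhinitis,19216,1.96,22523,8.12,5,other
Alopecia areata,821,0.08,632,0.23,75,other
Alzheimer's,9073,0.93,2444,0.88,179,aged
Amyotrophic lateral sclerosis,2182,0.22,276,0.10,70,aged
Ankylosing spondylitis,510,0.05,532,0.19,38,adulthood
Aortic aneurysm,2990,0.31,5401,1.95,22,aged
Attention deficit,6964,0.71,5043,1.82,93,youth
Autism,481,0.05,2423,0.87,218,youth
Behcet's s.,53,0.01,82,0.03,42,other
Bipolar disorder,12373,1.26,7179,2.59,185,adulthood
Cardiomyopathy,11457,1.17,8212,2.96,4,aged
Celiac sprue,1954,0.20,1267,0.46,45,other
Cholelithiasis,15353,1.57,8095,2.92,5,aged
Depression,27085,2.77,8283,2.99,155,adulthood
Diabetes type 1,19372,1.98,5116,1.84,323,other
Diabetes type 2,60815,6.21,40176,14.49,254,aged
Epilepsy,12099,1.24,12095,4.36,9,neonate
Goiter,10820,1.11,9201,3.32,5,adulthood
Gout,192,0.02,106,0.04,12,aged
HIV,6138,0.63,1073,0.39,92,adulthood
Hepatitis B,5757,0.59,3212,1.16,14,adulthood
Hepatitis C,18421,1.88,6583,2.37,40,aged
Hypertrophic cardiomyopathy,603,0.06,831,0.30,4,adulthood
Kawasaki's d.,495,0.05,328,0.12,66,youth
Migraine,8049,0.82,12593,4.54,18,adulthood
Moyamoya,130,0.01,557,0.20,8,other
Multiple sclerosis,14979,1.53,1685,0.61,261,adulthood
Parkinson's d.,6116,0.62,2839,1.02,151,aged
Psoriasis,4577,0.47,3249,1.17,104,adulthood
Rheumatoid arthritis,7333,0.75,4775,1.72,348,aged
Schizophrenia,11256,1.15,1935,0.70,208,adulthood
Sjogren's s.,348,0.04,893,0.32,7,aged
Systemic lupus erythematosus,3194,0.33,2090,0.75,175,adulthood
Tuberculosis,66569,6.80,912,0.33,32,adulthood
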