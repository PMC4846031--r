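disease1,disease2,source,obs_exp,p_value,direction
Ankylosing spondylitis,Psoriasis,columbia,7.13,6.22E-10,over
Ankylosing spondylitis,Psoriasis,stanford,2.57,6.85E-04,over
Ankylosing spondylitis,Systemic lupus erythematosus,columbia,46.88,3.13E-102,over
Ankylosing spondylitis,Systemic lupus erythematosus,stanford,3.24,2.56E-04,over
Bipolar disorder,Depression,columbia,16.27,0.00E+00,over
Bipolar disorder,Depression,stanford,7.07,0.00E+00,over
Bipolar disorder,Schizophrenia,columbia,22.34,0.00E+00,over
Bipolar disorder,Schizophrenia,stanford,10.16,0.00E+00,over
Rheumatoid arthritis,Sjogren's s.,columbia,35.29,2.33E-111,over
Rheumatoid arthritis,Sjogren's s.,stanford,10.92,1.51E-117,over
Alcoholism,Goiter,columbia,0.501,1.55E-22,under
Alcoholism,Goiter,stanford,0.297,6.16E-61,under
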