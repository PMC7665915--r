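variable,level,users,nonusers
gender,male,14607,29276
gender,female,18900,26365
age_band,0-20,12572,22941
age_band,21-40,10350,12869
age_band,41+,10585,19831
urbanization,1,19229,33689
urbanization,2,11362,17205
urbanization,3,2916,4747
insured_level,0-19999,21110,37326
insured_level,20000-39999,8485,12242
insured_level,40000+,3912,6073
atopic_dermatitis,yes,5957,9275
asthma,yes,4178,9836
chronic_sinusitis,yes,1311,1720
antihistamine_1st,yes,10614,18496
antihistamine_2nd,yes,26280,49693
decongestant,yes,8384,13229
intranasal_antihistamine,yes,157,422
intranasal_corticosteroid,yes,6156,14587
lra,yes,1095,2723
n_med_types,0,5097,2672
n_med_types,1,11613,21234
n_med_types,2,10691,19975
n_med_types,3+,6106,11761
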