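# Published corpus reporting figures (count, denominator, printed percent at
# the printed number of decimal places) used to validate the percent
# arithmetic of the aggregation module. Only pairs whose printed percent is
# exactly reproduced by half-up rounding are included; the source report
# rounds a minority of its figures inconsistently (apparent truncation) and
# those pairs are omitted here.
label	count	den	digits	printed
articles_with_theme	11927	22361	1	53.3
no_abstract	1543	23904	2	6.45
excluded_2021	113	11927	2	0.95
hiv	1493	11814	2	12.64
mortality	940	11814	2	7.96
alcohol_use	837	11814	2	7.08
treatment	818	11814	2	6.92
age	721	11814	1	6.1
mental_illness	704	11814	2	5.96
hepatitis_c	520	11814	1	4.4
tuberculosis	396	11814	2	3.35
crime	389	11814	2	3.29
injury	351	11814	2	2.97
offense	329	11814	2	2.78
delinquency	314	11814	2	2.66
recidivism	267	11814	2	2.26
gender	252	11814	2	2.13
youth	240	11814	2	2.03
hepatitis_b	210	11814	2	1.78
cat_infectious	2949	11814	2	24.96
cat_mental	2840	11814	2	24.04
cat_aod	2433	11814	2	20.59
cat_education	172	11814	2	1.46
cat_other	2552	11814	1	21.6
infect_1990	26	74	0	35
mental_1990	6	74	0	8
mental_2004	100	347	1	28.8
mh_mental_illness	704	2840	2	24.79
mh_depression	322	2840	2	11.34
mh_aspd	194	2840	2	6.83
mh_ptsd	178	2840	2	6.27
mh_adhd	135	2840	2	4.75
mh_psychopathy	117	2840	2	4.12
mh_depressive_symptom	110	2840	2	3.87
inf_hiv	1493	2949	2	50.63
inf_hcv	520	2949	2	17.63
inf_tb	396	2949	2	13.43
inf_hbv	210	2949	2	7.12
inf_sti	113	2949	2	3.83
inf_covid	108	2949	2	3.66
inf_chlamydia	93	2949	2	3.15
inf_std	85	2949	2	2.88
inf_malaria	66	2949	2	2.24
inf_hepatitis	65	2949	1	2.2
aod_substance	1533	2433	0	63
aod_alcohol	837	2433	1	34.4
aod_cannabis	88	2433	2	3.62
aod_cocaine	41	2433	2	1.69
aod_adolescent	30	2433	2	1.23
aod_nicotine	13	2433	2	0.53
aod_alc_harm	11	2433	2	0.45
aod_heroin	11	2433	2	0.45
inc_high	10083	11814	2	85.35
inc_upper_middle	740	11814	2	6.26
inc_lower_middle	435	11814	2	3.68
inc_low	91	11814	2	0.77
inc_no_country	489	11814	2	4.14
hi_mental	2590	10083	2	25.69
lm_mental	41	435	1	9.4
low_mental	16	91	0	18
low_infect	47	91	0	52
hi_aod	2182	10083	2	21.64
low_aod	4	91	0	4
low_healthcare	13	91	0	14
hi_healthcare	794	10083	2	7.87
um_healthcare	41	740	1	5.5
cat_healthcare	911	11814	2	7.71
cat_sdh	1147	11814	2	9.71
womens	13	11814	2	0.11
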