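matrix	metabolite	mean_control	mean_case	rsd_percent	log2_fd_printed
plasma	73.08939 @ 7.5	3.56E+03	3.33E+03	18.22	-0.10
plasma	Ethanolamine	1.26E+04	1.15E+04	20.22	-0.13
plasma	475.22627 @ 6.76	3.27E+03	3.44E+03	15.23	0.07
plasma	N-Lauroylglycine	2.59E+03	2.45E+03	9.55	-0.08
plasma	Alpha-N-Phenylacetyl-L-glutamine	2.11E+04	2.98E+04	85.53	0.50
plasma	PC(35:6)	1.98E+04	1.52E+04	57.06	-0.38
plasma	Sarcosine	8.01E+05	8.36E+05	17.06	0.06
plasma	SM(d30:1)	6.69E+03	6.40E+03	28.79	-0.0624
plasma	SM(d32:1)	1.94E+05	1.86E+05	22.44	-0.0574
plasma	SM(d39:1)	2.25E+04	2.09E+04	29.20	-0.1101
plasma	Glu-Ile	5.45E+03	5.07E+03	20.73	-0.1038
plasma	535.24187 @ 5.4	4.13E+03	3.89E+03	12.67	-0.0853
plasma	186.11894 @ 0.95	2.38E+04	1.98E+04	66.10	-0.2669
plasma	1,3-Dimethyluracil	4.08E+03	5.42E+03	62.62	0.40917
plasma	PC(44:5)	1.15E+04	1.35E+04	36.99	0.23385
plasma	PC(44:6)	7.41E+03	8.84E+03	33.55	0.25355
plasma	PE(34:1)	3.52E+03	2.82E+03	41.11	-0.3214
plasma	Arg-Ala	1.00E+04	1.29E+04	69.02	0.35912
plasma	Lyso-PAF C-16	2.53E+04	2.79E+04	19.11	0.14038
plasma	354.92649 @ 0.11	4.37E+04	4.24E+04	6.58	-0.0435
csf	Prolyl-Tyrosine	6.99E+03	9.46E+03	53.98	0.44
csf	Sarcosine	2.14E+04	1.96E+04	19.72	-0.13
csf	Ser-Glu	7.46E+03	8.97E+03	39.14	0.26
csf	432.31975 @ 6.13	6.45E+03	5.95E+03	16.59	-0.12
csf	Leu-Trp-Trp	6.16E+03	5.51E+03	14.66	-0.16
csf	Alpha-N-Phenylacetyl-L-glutamine	2.56E+04	3.55E+04	56.61	0.47
csf	Betaine	4.95E+05	4.54E+05	15.93	-0.13
csf	517.24582 @ 6.8	7.03E+03	7.42E+03	10.32	0.08
csf	S-(2-Methylpropionyl)-dihydrolipoamide-E	7.35E+03	5.98E+03	37.10	-0.30
csf	3-ketosphingosine	6.40E+03	6.87E+03	17.37	0.10
csf	972.90985 @ 12.31	5.21E+03	4.91E+03	12.33	-0.09
csf	(+)-gamma-Hydroxy-L-homoarginine	6.30E+04	6.49E+04	5.43	0.04
csf	O-Adipoylcarnitine	5.96E+03	5.46E+03	25.71	-0.12
csf	Dimethylglycine	8.06E+04	7.29E+04	17.91	-0.15
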