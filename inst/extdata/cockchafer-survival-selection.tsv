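first_year_survival	adult_survival	deviance	parameters	dAIC	weight
year	blythii: .; myotis: cockchafer	8747.12	52	0.00	0.261
year	blythii: .; myotis: .	8749.19	51	0.07	0.251
year	blythii: cockchafer; myotis: .	8748.47	52	1.35	0.132
year	blythii: cockchafer; myotis: cockchafer	8746.72	53	1.60	0.117
blythii: cockchafer; myotis: year	blythii: .; myotis: cockchafer	8746.43	54	3.31	0.049
blythii: year; myotis: cockchafer	blythii: .; myotis: cockchafer	8746.73	54	3.62	0.043
blythii: cockchafer; myotis: year	blythii: .; myotis: .	8749.20	53	4.08	0.034
blythii: cockchafer; myotis: cockchafer	blythii: .; myotis: cockchafer	8765.89	45	4.78	0.024
blythii: cockchafer; myotis: year	blythii: cockchafer; myotis: cockchafer	8746.16	55	5.05	0.021
blythii: year; myotis: cockchafer	blythii: cockchafer; myotis: cockchafer	8746.31	55	5.19	0.019
blythii: cockchafer; myotis: year	blythii: cockchafer; myotis: .	8748.67	54	5.55	0.016
blythii: year; myotis: cockchafer	blythii: .; myotis: .	8751.80	53	6.69	0.009
blythii: cockchafer; myotis: cockchafer	blythii: cockchafer; myotis: cockchafer	8765.87	46	6.75	0.009
blythii: cockchafer; myotis: cockchafer	blythii: .; myotis: .	8770.56	44	7.45	0.006
blythii: year; myotis: cockchafer	blythii: cockchafer; myotis: .	8750.99	54	7.87	0.005
blythii: cockchafer; myotis: cockchafer	blythii: cockchafer; myotis: .	8770.41	45	9.29	0.003
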