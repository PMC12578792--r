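roi	mean	sd	df	t	p	q	d	power
lMFG	1.941e-02	3.033e-01	11	0.222	0.414	0.115	0.06	0.08
lSTS	2.882e-01	4.224e-01	10	2.263	0.024	0.021	0.68	0.72
lTPJ	3.181e-01	4.767e-01	10	2.213	0.026	0.021	0.67	0.70
rMFG	1.204e-01	5.961e-01	10	0.670	0.259	0.087	0.20	0.16
rSTS	1.593e-01	3.784e-01	10	1.396	0.096	0.054	0.42	0.39
rTPJ	1.009e-01	4.359e-01	10	0.768	0.230	0.087	0.23	0.19
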