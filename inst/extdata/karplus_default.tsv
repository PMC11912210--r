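# Editable Karplus parameter defaults (Hz, degrees).
# Representative literature-style values for the five couplings used to
# constrain guest-residue backbone ensembles; replace freely with your own
# parametrization.  NA marks unavailable parameter uncertainties.
coupling_name	A	B	C	theta0	depends_on	s_A	s_B	s_C
3J(HN,HA)	7.09	-1.42	1.55	-60	phi	0.12	0.09	0.08
3J(HN,C')	4.29	-1.01	0.00	180	phi	0.13	0.10	0.07
3J(HA,C')	3.72	-2.18	1.28	120	phi	0.19	0.15	0.10
3J(HN,CB)	3.06	-0.74	0.13	60	phi	0.14	0.11	0.06
1J(N,CA)	0.80	-0.66	10.70	0	psi	NA	NA	NA
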