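name	rho	ri	mu_a	mu_s	g_hg	cp	alpha_d	wb	eps_re	eps_im	mu_a_nano	composition
pancreas	1040	1.394	0.0388	196.8	0.9	3554.6	0.14	0	1.767	0	0	H:1.06,C:1.69,N:0.22,O:6.94,Na:0.02,P:0.02,S:0.01,Cl:0.02,K:0.02
tumor_gnr	1040.012	1.3939	0.0388	196.8	0.9	3605.7	0.16	0	-24.718	3.6581	1.685	H:1.059,C:1.68,N:0.219,O:6.939,Na:0.019,P:0.019,S:0.0099,Cl:0.019,K:0.019,Au:0.0012
water	998	1.33	0.0204	0	0	4182	0.143	0	1.769	0	0	H:0.111894,O:0.888106
air	1.2	1	0	0	0	1006	19	0	1	0	0	N:0.755,O:0.232,Ar:0.013
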