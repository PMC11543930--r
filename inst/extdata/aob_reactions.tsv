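index	enzyme	multiplicity	dg0_const	dg0_a	dg0_b	equation
1	ACR	1	16.900	NA	NA	C4H10 + CoM-S-S-CoB = C4H9-S-CoM + HS-CoB
2	Hdr-FrhB	1	7.141	NA	NA	HS-CoM + HS-CoB + 2 Fd_red + 2 H+ + 2 F420 = CoM-S-S-CoB + 2 Fd_ox + 2 F420H2
3	unknown	1	NA	-386	-55.801	C4H9-S-CoM + CoA + H2O + 2 X = Butyryl-CoA + HS-CoM + 2 XH2
4	Bcd-Etf	1	25.090	NA	NA	Butyryl-CoA + 2 NAD+ + 2 Fd_red = Crotonyl-CoA + 2 NADH + 2 Fd_ox
5	Ech	1	0.300	NA	NA	Crotonyl-CoA + H2O = 3-Hydroxybutyryl-CoA
6	HADH	1	12.545	NA	NA	3-Hydroxybutyryl-CoA + NAD+ = Acetoacetyl-CoA + NADH + H+
7	ACAT	1	-28.100	NA	NA	Acetoacetyl-CoA + CoA = 2 Acetyl-CoA
8	NDH	5	-46.320	NA	NA	NADH + H+ + MQ = NAD+ + MQH2
9	ACS-CODH	2	66.114	NA	NA	Acetyl-CoA + H4MPT + 2 Fd_ox + H2O = CH3-H4MPT + CoA + CO2 + 2 Fd_red + 2 H+
10	Met	2	1.140	NA	NA	CH3-H4MPT + NAD+ = CH2-H4MPT + NADH + H+
11	Mtd	2	-6.500	NA	NA	CH2-H4MPT + F420 + H+ = CH-H4MPT + F420H2
12	Mch	2	2.000	NA	NA	CH-H4MPT + H2O = CHO-H4MPT + H+
13	Ftr	2	-21.100	NA	NA	CHO-H4MPT + MF = CHO-MF + H4MPT
14	Fwd	2	0.598	NA	NA	CHO-MF + H2O + 2 Fd_ox = CO2 + MF + 2 H+ + 2 Fd_red
15	Fqo	4	-50.180	NA	NA	F420H2 + MQ = F420 + MQH2
16	Nuo	2	-81.060	NA	NA	2 Fd_red + 2 H+ + MQ = 2 Fd_ox + MQH2
17	MHCs	11	NA	-193	-15.440	MQH2 + X = MQ + XH2
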