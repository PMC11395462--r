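term	r	R	n	N	p
voltage-gated cation channel activity	11	25	138	15288	8.66e-17
voltage-gated calcium channel activity	8	25	35	15288	3.35e-16
voltage-gated ion channel activity	11	25	188	15288	2.78e-15
voltage-gated channel activity	11	25	188	15288	2.78e-15
cation channel activity	12	25	289	15288	6.93e-15
ion gated channel activity	12	25	323	15288	2.63e-14
gated channel activity	12	25	323	15288	2.63e-14
calcium channel activity	9	25	109	15288	6.32e-14
calcium ion transmembrane transporter activity	9	25	128	15288	2.77e-13
ion channel activity	12	25	415	15288	5.17e-13
substrate-specific channel activity	12	25	425	15288	6.85e-13
high voltage-gated calcium channel activity	5	25	9	15288	9.58e-13
passive transmembrane transporter activity	12	25	450	15288	1.34e-12
channel activity	12	25	450	15288	1.34e-12
divalent inorganic cation transmembrane transporter activity	9	25	155	15288	1.59e-12
transmembrane transporter activity	15	25	972	15288	1.81e-12
cation transmembrane transporter activity	13	25	618	15288	2.26e-12
ion transmembrane transporter activity	14	25	825	15288	4.08e-12
metal ion transmembrane transporter activity	11	25	401	15288	1.13e-11
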