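term	r	R	n	N	p
serotonin binding	7	25	11	15288	4.08e-18
amine binding	7	25	13	15288	2.12e-17
drug binding	11	25	130	15288	4.4e-17
serotonin receptor activity	7	25	15	15288	7.93e-17
G-protein coupled amine receptor activity	7	25	42	15288	3.23e-13
transmembrane signaling receptor activity	14	25	1196	15288	5.86e-10
dopamine binding	4	25	10	15288	1.16e-9
signaling receptor activity	14	25	1299	15288	1.74e-9
signal transducer activity	15	25	1617	15288	2.55e-9
molecular transducer activity	15	25	1617	15288	2.55e-9
dopamine neurotransmitter receptor activity, coupled via Gi/Go	3	25	3	15288	3.86e-9
catecholamine binding	4	25	14	15288	5.5e-9
G-protein coupled receptor activity	11	25	812	15288	1.99e-8
receptor activity	14	25	1583	15288	2.28e-8
dopamine neurotransmitter receptor activity	3	25	5	15288	3.85e-8
extracellular ligand-gated ion channel activity	5	25	74	15288	1.14e-7
excitatory extracellular ligand-gated ion channel activity	4	25	49	15288	1.12e-6
ligand-gated channel activity	5	25	145	15288	3.27e-6
ligand-gated ion channel activity	5	25	145	15288	3.27e-6
neurotransmitter binding	3	25	24	15288	7.64e-6
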