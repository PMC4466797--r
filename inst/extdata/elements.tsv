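# symbol	atomic_number	mass	polarizability_A3
# standard atomic weights; Miller atomic polarizabilities (cubic Angstrom)
H	1	1.008	0.667
B	5	10.81	3.03
C	6	12.011	1.76
N	7	14.007	1.10
O	8	15.999	0.802
F	9	18.998	0.557
Na	11	22.990	23.6
Mg	12	24.305	10.6
Si	14	28.085	5.38
P	15	30.974	3.63
S	16	32.06	2.90
Cl	17	35.45	2.18
K	19	39.098	43.4
Ca	20	40.078	22.8
Br	35	79.904	3.05
I	53	126.904	5.35
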