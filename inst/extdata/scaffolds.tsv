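# name	template
# drug-like scaffolds; {R1}/{R2} mark substitution slots
benzene	c1ccc({R1})cc1
benzene_14	c1cc({R2})ccc1{R1}
benzene_13	c1cc({R1})cc({R2})c1
pyridine	c1ccnc({R1})c1
pyrimidine	c1cnc({R1})nc1
furan	c1ccc({R1})o1
thiophene	c1ccc({R1})s1
pyrrole	c1ccc({R1})[nH]1
pyrazole	c1cc({R1})[nH]n1
imidazole	c1cnc({R1})[nH]1
naphthalene	c1ccc2cc({R1})ccc2c1
quinoline	c1ccc2nc({R1})ccc2c1
indole	c1ccc2c(c1)cc({R1})[nH]2
benzofuran	c1ccc2c(c1)cc({R1})o2
biphenyl	c1ccc(-c2ccc({R1})cc2)cc1
cyclohexane	C1CCC({R1})CC1
cyclopentane	C1CCC({R1})C1
piperidine	C1CCN({R1})CC1
piperazine	C1CN({R1})CCN1{R2}
morpholine	C1COCCN1{R1}
tetrahydrofuran	C1CCC({R1})O1
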