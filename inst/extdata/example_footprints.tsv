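name	formula	mw	inchi	kegg	chebi	pubchem	class	compartment
sphinganine	C18H39NO2	301.5		C00836	16566	91486	sphingolipids	e
phytosphingosine	C18H39NO3	317.5		C12144	46961	122121	sphingolipids	e
sphingosine	C18H39NO2	299.5		C00319	16393	5280335	sphingolipids	e
ceramide	C34H69NO3	539.9		C00195	17761	5283565	sphingolipids	e
adenosine	C10H13N5O4	267.2		C00212	16335	60961	nucleosides	e
methyl jasmonate	C13H20O3	224.3			25524	5281929	fatty acyls	e
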