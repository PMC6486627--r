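# Versioned domain-definition config. Author residue numbering.
# chain "*" applies to every protein chain of the structure.
# ctPrp22 entries follow the deposited annotation (RecA1 557-733,
# RecA2 734-909, WH 910-977, HB 978-1091, OB 1092-1175).
# Homologs analysed against these (e.g. Prp43, Prp2) need their own rows,
# derived once by sequence alignment to the ctPrp22 intervals, before the
# cross-protein comparisons run; they are deliberately not guessed here.
structure_id	chain	domain	start	end
ctPrp22	*	Nterm	549	556
ctPrp22	*	RecA1	557	733
ctPrp22	*	RecA2	734	909
ctPrp22	*	WH	910	977
ctPrp22	*	HB	978	1091
ctPrp22	*	OB	1092	1175
6I3O	*	RecA1	557	733
6I3O	*	RecA2	734	909
6I3P	*	RecA1	557	733
6I3P	*	RecA2	734	909
6QIC	*	RecA1	557	733
6QIC	*	RecA2	734	909
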