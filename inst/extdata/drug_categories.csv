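drug,category
interferon beta,first_line
glatiramer acetate,first_line
teriflunomide,first_line
dimethyl fumarate,first_line
natalizumab,second_line
fingolimod,second_line
ocrelizumab,second_line
rituximab,second_line
alemtuzumab,second_line
cladribine,second_line
siponimod,second_line
methylprednisolone,relapse_drug
prednisolone,relapse_drug
ahsct,stem_cell
autologous stem cell transplant,stem_cell
baclofen,other
fampridine,other
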