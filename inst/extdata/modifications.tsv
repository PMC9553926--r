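code	name	formula	parent	pyrimidine_derived	guanosine_derived	ce_reactive	rnase_a_site	rnase_t1_site	deamination_product	mrm_loss
A	adenosine	C10H12N5O6P	A	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
G	guanosine	C10H12N5O7P	G	FALSE	TRUE	FALSE	FALSE	TRUE	FALSE
C	cytidine	C9H12N3O7P	C	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
U	uridine	C9H11N2O8P	U	TRUE	FALSE	FALSE	TRUE	FALSE	TRUE
Y	pseudouridine	C9H11N2O8P	U,C	TRUE	FALSE	TRUE	TRUE	FALSE	TRUE	H4O2
D	dihydrouridine	C9H13N2O8P	U	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
m5U	5-methyluridine	C10H13N2O8P	U	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
Q	queuosine	C17H22N5O9P	G	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
ms2io6A	2-methylthio-N6-(cis-hydroxyisopentenyl)adenosine	C16H22N5O7PS	A	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
I	inosine	C10H11N4O7P	A,G	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
Am	2'-O-methyladenosine	C11H14N5O6P	A	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	C6H10O4
Gm	2'-O-methylguanosine	C11H14N5O7P	G	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE	C6H10O4
Cm	2'-O-methylcytidine	C10H14N3O7P	C	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	C6H10O4
Um	2'-O-methyluridine	C10H13N2O8P	U	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	C6H10O4
U18	uridine-18O	C9H11N2O7[18O]P	U,C	TRUE	FALSE	FALSE	TRUE	FALSE	FALSE
Y18	pseudouridine-18O	C9H11N2O7[18O]P	U,C	TRUE	FALSE	TRUE	TRUE	FALSE	FALSE	H4O2
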