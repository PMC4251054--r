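keyword,priority,type
universi,10,university
institut,20,university
istituto,20,university
college,30,university
academy,30,university
polytechnic,30,university
school,40,department
facult,40,department
department,45,department
hospital,50,hospital
hopital,50,hospital
klinik,50,hospital
clinic,55,hospital
ospedale,50,hospital
infirmary,55,hospital
medical center,60,hospital
center,70,other
centre,70,other
foundation,75,other
laborator,80,other
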