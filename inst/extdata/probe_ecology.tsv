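probe_id	eco_class	grouping	sub_probe	parent_probe
Bacteroides_Prevotella	M	major	FALSE	
Ruminococcus_bromii	M	major	FALSE	
Ruminococcus_albus	M	major	FALSE	
Faecalibacterium_prausnitzii	M	major	FALSE	
Oscillospira_guillermondii	M	major	FALSE	
Clostridium_IX	M	major	FALSE	
Veillonella	M	major	TRUE	Clostridium_IX
Clostridium_XIVa	M	major	FALSE	
Eubacterium_rectale	M	major	TRUE	Clostridium_XIVa
Bifidobacteriaceae	M	minor	FALSE	
Bifidobacterium_longum	M	minor	TRUE	Bifidobacteriaceae
Lactobacillaceae	M	minor	FALSE	
Lactobacillus_plantarum	M	minor	TRUE	Lactobacillaceae
Lactobacillus_casei	M	minor	TRUE	Lactobacillaceae
Lactobacillus_salivarius	M	minor	TRUE	Lactobacillaceae
Bacillus_clausii	M	minor	FALSE	
Bacillus_subtilis	M	minor	FALSE	
Fusobacterium	M	minor	FALSE	
Cyanobacteria	M	minor	FALSE	
Clostridium_XI	O	opportunistic	FALSE	
Clostridium_difficile	O	opportunistic	TRUE	Clostridium_XI
Clostridium_I_II	O	opportunistic	FALSE	
Clostridium_perfringens	O	opportunistic	TRUE	Clostridium_I_II
Enterococcus_faecalis	O	opportunistic	FALSE	
Enterococcus_faecium	O	opportunistic	FALSE	
Bacillus_cereus	P	opportunistic	FALSE	
Enterobacteriaceae	O/P	opportunistic	FALSE	
Yersinia_enterocolitica	O/P	opportunistic	TRUE	Enterobacteriaceae
Proteus	O/P	opportunistic	TRUE	Enterobacteriaceae
Campylobacter	P	opportunistic	FALSE	
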