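level	label	parent_labels
KW	Phosphoprotein	
KW	Glycoprotein	
KW	Disulfide bond	
KW	Nucleotide-binding	
KW	Acetylation	
KW	Lipoprotein	
KW	Methylation	
KW	Ubl conjugation	
KW	D-amino acid	
KW	Palmitoylation	
KW	Amidation	
KW	Citrullination	
KW	Sulfation	
KW	Hydroxylation	
KW	Uncategorized	
FT	Phosphoserine	Phosphoprotein
FT	Phosphothreonine	Phosphoprotein
FT	Phosphotyrosine	Phosphoprotein
FT	Phosphohistidine	Phosphoprotein
FT	N6-acetyllysine	Acetylation
FT	N-acetylalanine	Acetylation
FT	N-acetylmethionine	Acetylation
FT	N6-succinyllysine	Uncategorized
FT	N6-(pyridoxal phosphate)lysine	Uncategorized
FT	N6-carboxylysine	Uncategorized
FT	N5-methylglutamine	Methylation
FT	Glycyl lysine isopeptide	Ubl conjugation
FT	Glycyl lysine isopeptide (Lys-Gly)	Ubl conjugation
FT	Interchain with G-Cter in ubiquitin	Ubl conjugation
FT	S-palmitoyl cysteine	Palmitoylation|Lipoprotein
FT	N-palmitoyl cysteine	Palmitoylation|Lipoprotein
FT	S-diacylglycerol cysteine	Lipoprotein
FT	N-linked glycosylation	Glycoprotein
FT	O-linked glycosylation	Glycoprotein
FT	Citrulline	Citrullination
FT	Cysteine persulfide	Uncategorized
FT	D-4-hydroxyvaline	D-amino acid
FT	D-valine	D-amino acid
FT	Sulfotyrosine	Sulfation
FT	4-hydroxyproline	Hydroxylation
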