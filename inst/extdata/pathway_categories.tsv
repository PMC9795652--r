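pathway	category
Glycolysis	carbohydrate
Galactose_metabolism	carbohydrate
Propanoate_metabolism	carbohydrate
Butanoate_metabolism	carbohydrate
Pyruvate_metabolism	carbohydrate
Pentose_phosphate_pathway	carbohydrate
Cysteine_methionine_metabolism	amino_acid
Glycine_serine_threonine_metabolism	amino_acid
Tryptophan_metabolism	amino_acid
Secondary_bile_acid_biosynthesis	lipid
Glycerolipid_metabolism	lipid
Fatty_acid_biosynthesis	lipid
Xenobiotics_degradation	xenobiotic
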