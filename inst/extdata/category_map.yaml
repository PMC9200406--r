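# Default mapping from HMDB-style subclass/superclass terms to the five
# broad metabolite categories used for category-wise z-scoring and
# classification. Matching is case-insensitive; subclass is consulted
# first, then superclass. Unmapped terms fall back to
# Miscellaneous/secondary with a warning.
monosaccharides: Carbohydrates/CCM
disaccharides: Carbohydrates/CCM
carbohydrates and carbohydrate conjugates: Carbohydrates/CCM
organooxygen compounds: Carbohydrates/CCM
sugar acids and derivatives: Carbohydrates/CCM
sugar phosphates: Carbohydrates/CCM
tricarboxylic acids and derivatives: Carbohydrates/CCM
tca acid derivatives: Carbohydrates/CCM
glycolysis intermediates: Carbohydrates/CCM
pentose phosphates: Carbohydrates/CCM
amino acids, peptides, and analogues: Amino acids
amino acids and derivatives: Amino acids
carboximidic acids and derivatives: Amino acids
amines: Amino acids
ureas: Amino acids
fatty acids and conjugates: Fatty acids
fatty acid esters: Fatty acids
fatty acyls: Fatty acids
lineolic acids and derivatives: Fatty acids
eicosanoids: Fatty acids
acyl carnitines: Fatty acids
purines and purine derivatives: Nucleotides
pyrimidines and pyrimidine derivatives: Nucleotides
nucleosides, nucleotides, and analogues: Nucleotides
purine nucleosides: Nucleotides
pyrimidine nucleosides: Nucleotides
purine nucleotides: Nucleotides
pyrimidine nucleotides: Nucleotides
benzene and substituted derivatives: Miscellaneous/secondary
phenols: Miscellaneous/secondary
indoles and derivatives: Miscellaneous/secondary
alcohols and polyols: Miscellaneous/secondary
hydroxy acids and derivatives: Miscellaneous/secondary
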