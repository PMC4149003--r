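attribute	value
genome_size_bp	2319586
gc_bp	1526287
coding_bp	1997199
replicons	1
total_genes	2054
predicted_genes_text	2057
rna_genes	54
rrna_operons	1
protein_coding_genes	2003
genes_with_function_prediction	1503
genes_assigned_to_cogs	1370
genes_with_peptide_signals	40
genes_with_transmembrane_helices	471
orfans	165
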