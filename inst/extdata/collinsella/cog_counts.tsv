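code	count	description
J	135	Translation
A	0	RNA processing and modification
K	113	Transcription
L	79	Replication, recombination and repair
B	0	Chromatin structure and dynamics
D	18	Cell cycle control, mitosis and meiosis
Y	0	Nuclear structure
V	53	Defense mechanisms
T	29	Signal transduction mechanisms
M	81	Cell wall/membrane biogenesis
N	2	Cell motility
Z	0	Cytoskeleton
W	0	Extracellular structures
U	10	Intracellular trafficking and secretion
O	39	Posttranslational modification, protein turnover, chaperones
C	69	Energy production and conversion
G	189	Carbohydrate transport and metabolism
E	123	Amino acid transport and metabolism
F	43	Nucleotide transport and metabolism
H	28	Coenzyme transport and metabolism
I	28	Lipid transport and metabolism
P	46	Inorganic ion transport and metabolism
Q	3	Secondary metabolites biosynthesis, transport and catabolism
R	165	General function prediction only
S	117	Function unknown
-	500	Not in COGs
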