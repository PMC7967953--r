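label	fine_id	fine_name	coarse_id	coarse_name	n_fine	n_coarse	N_fine	N_coarse	m_fine	m_coarse	sig_digits
cysteine	CYSTSYN-PWY	L-cysteine biosynthesis	map00270	Cysteine and methionine metabolism	3	34	1096	1686	354	119	2
arginine	ARGSYN-PWY	Arginine biosynthesis	map00220	Arginine biosynthesis	12	18	1096	1686	354	119	2
selenocysteine	PWY0-901	L-selenocysteine biosynthesis I	map00450	Selenocompound metabolism	4	17	1096	1686	354	119	2
valine	VALSYN-PWY	L-valine biosynthesis	map00290	Valine, leucine, and isoleucine biosynthesis	9	16	1096	1686	354	119	2
purine	PWY-7222	Guanosine deoxyribonucleotides de novo biosynthesis II	map00230	Purine metabolism	10	78	1096	1686	354	119	3
pyrimidine	PWY-7184	Pyrimidine deoxyribonucleotides de novo biosynthesis I	map00240	Pyrimidine metabolism	13	51	1096	1686	354	119	3
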