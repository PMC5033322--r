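id	species	role	claimed_species	type_strain
HYC-10T	B. xiamenensis	train	B. xiamenensis	yes
B4133	B. altitudinis	test	B. pumilus	no
C772	B. altitudinis	train	B. aerophilus	no
INR7	B. altitudinis	test	B. pumilus	no
B-388	B. altitudinis	train	B. altitudinis	no
LAMA_585	B. altitudinis	train	B. stratosphericus	no
MTCC_B6033	B. altitudinis	test	B. pumilus	no
41KF2bT	B. altitudinis	train	B. altitudinis	yes
BA06	B. altitudinis	test	B. pumilus	no
S-1	B. altitudinis	test	B. pumilus	no
B4129	B. safensis	test	B. pumilus	no
S9	B. safensis	train	B. safensis	no
WP8	B. safensis	test	B. pumilus	no
FO-36bT	B. safensis	train	B. safensis	yes
B4134	B. safensis	test	B. pumilus	no
B4107	B. safensis	test	B. pumilus	no
CCMA-560	B. safensis	test	B. pumilus	no
VK	B. safensis	train	B. safensis	no
CFA06	B. safensis	train	B. safensis	no
Fairview	B. safensis	test	B. pumilus	no
7P	B. pumilus	test	B. pumilus	no
SAFR-032	B. pumilus	train	B. pumilus	no
ATCC_7061T	B. pumilus	train	B. pumilus	yes
B4127	B. pumilus	test	B. pumilus	no
FZB42T	B. amyloliquefaciens	query	B. amyloliquefaciens	yes
168T	B. subtilis	query	B. subtilis	yes
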