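species_id	ps_index	clade_name	approx_age_mya	role
ecoli	1	cellular_organisms	3500	non_vertebrate
bsubtilis	1	cellular_organisms	3500	non_vertebrate
mjannaschii	1	cellular_organisms	3500	non_vertebrate
ddiscoideum	2	eukaryota	1850	non_vertebrate
tthermophila	2	eukaryota	1850	non_vertebrate
ehistolytica	2	eukaryota	1850	non_vertebrate
scerevisiae	3	opisthokonta	1100	non_vertebrate
spombe	3	opisthokonta	1100	non_vertebrate
ncrassa	3	opisthokonta	1100	non_vertebrate
srosetta	4	holozoa	950	non_vertebrate
mbrevicollis	4	holozoa	950	non_vertebrate
cowczarzaki	4	holozoa	950	non_vertebrate
aqueenslandica	5	metazoa	800	non_vertebrate
mleidyi	5	metazoa	800	non_vertebrate
nvectensis	6	eumetazoa	700	non_vertebrate
hvulgaris	6	eumetazoa	700	non_vertebrate
celegans	7	bilateria	650	non_vertebrate
dmelanogaster	7	bilateria	650	non_vertebrate
lgigantea	7	bilateria	650	non_vertebrate
pcaudatus	7	bilateria	650	non_vertebrate
spurpuratus	8	deuterostomia	580	non_vertebrate
skowalevskii	8	deuterostomia	580	non_vertebrate
bfloridae	9	chordata	550	non_vertebrate
blanceolatum	9	chordata	550	non_vertebrate
cintestinalis	10	olfactores	545	non_vertebrate
csavignyi	10	olfactores	545	non_vertebrate
pmarinus	11	vertebrata	540	vertebrate
ccarcharias	12	gnathostomata	530	vertebrate
drerio	13	euteleostomi	460	vertebrate
xtropicalis	14	tetrapoda	440	vertebrate
ggallus	15	amniota	310	vertebrate
oanatinus	16	mammalia	180	vertebrate
sharrisii	16	mammalia	180	vertebrate
dnovemcinctus	17	eutheria	160	vertebrate
btaurus	17	eutheria	160	vertebrate
mmusculus	18	euarchontoglires	90	vertebrate
mmulatta	19	catarrhini	30	vertebrate
ptroglodytes	19	catarrhini	30	vertebrate
hsapiens	20	homini	6	vertebrate
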