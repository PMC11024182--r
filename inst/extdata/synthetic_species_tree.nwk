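((ecoli,bsubtilis,mjannaschii),((ddiscoideum,tthermophila,ehistolytica),((scerevisiae,spombe,ncrassa),((srosetta,mbrevicollis,cowczarzaki),((aqueenslandica,mleidyi),((nvectensis,hvulgaris),((celegans,dmelanogaster,lgigantea,pcaudatus),((spurpuratus,skowalevskii),((bfloridae,blanceolatum),((cintestinalis,csavignyi),(pmarinus,(ccarcharias,(drerio,(xtropicalis,(ggallus,((oanatinus,sharrisii),((dnovemcinctus,btaurus),(mmusculus,((mmulatta,ptroglodytes),hsapiens)))))))))))))))))));
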