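family,ref_position,ref_residue,lobe,conserved_set,salt_bridge,note
GbpA,33,R,N,R,TRUE,"literature-named: salt bridge to the GS-I amino terminus"
GbpA,36,N,N,N,FALSE,"synthetic placeholder (N-lobe contact)"
GbpA,65,D,N,D,FALSE,"synthetic placeholder (N-lobe contact)"
GbpA,107,K,N,K,FALSE,"synthetic placeholder (N-lobe contact)"
GbpA,110,E,N,E,FALSE,"synthetic placeholder (N-lobe contact)"
GbpA,138,Y,C,Y,FALSE,"literature-named: hydroxyl H-bonds D432, hydrophobic packing"
GbpA,355,W,C,W,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,380,A,C,A,FALSE,"literature-named: peptide N H-bonds GlyI carbonyl of GS-I"
GbpA,383,G,C,G,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,401,N,C,N,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,430,S,C,S,FALSE,"literature-named: H-bonds gamma-glutamyl carboxylate and amine"
GbpA,432,D,C,D,TRUE,"literature-named: salt bridge to GS-I amino terminus, positions Y138/Y521"
GbpA,469,M,C,M,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,473,E,C,E,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,495,S,C,S,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,517,H,C,H,FALSE,"synthetic placeholder (C-lobe contact)"
GbpA,521,Y,C,Y,FALSE,"literature-named: hydroxyl positioned by D432 for hydrophobic contact"
GbpA,524,K,C,K,FALSE,"synthetic placeholder (C-lobe contact)"
DppA,355,Y,N,Y,FALSE,"synthetic placeholder"
DppA,370,S,N,S,FALSE,"synthetic placeholder"
DppA,376,W,C,W,FALSE,"synthetic placeholder"
DppA,393,N,C,N,FALSE,"synthetic placeholder"
DppA,404,T,C,T,FALSE,"synthetic placeholder"
DppA,406,G,C,G,FALSE,"synthetic placeholder"
DppA,408,D,C,D,TRUE,"literature-named: salt bridge to the dipeptide amino terminus"
DppA,421,F,C,F,FALSE,"synthetic placeholder"
DppA,463,E,C,E,FALSE,"synthetic placeholder"
DppA,498,R,C,R,FALSE,"synthetic placeholder"
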