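codon,aa,fraction
AAA,K,0.48
AAC,N,0.48
AAG,K,0.52
AAT,N,0.52
ACA,T,0.31
ACC,T,0.2
ACG,T,0.15
ACT,T,0.34
AGA,R,0.35
AGC,S,0.13
AGG,R,0.2
AGT,S,0.16
ATA,I,0.24
ATC,I,0.35
ATG,M,1
ATT,I,0.41
CAA,Q,0.56
CAC,H,0.39
CAG,Q,0.44
CAT,H,0.61
CCA,P,0.33
CCC,P,0.12
CCG,P,0.17
CCT,P,0.38
CGA,R,0.12
CGC,R,0.07
CGG,R,0.09
CGT,R,0.17
CTA,L,0.1089
CTC,L,0.1683
CTG,L,0.1089
CTT,L,0.2574
GAA,E,0.52
GAC,D,0.32
GAG,E,0.48
GAT,D,0.68
GCA,A,0.2673
GCC,A,0.1584
GCG,A,0.1386
GCT,A,0.4356
GGA,G,0.3663
GGC,G,0.1386
GGG,G,0.1584
GGT,G,0.3366
GTA,V,0.1485
GTC,V,0.1881
GTG,V,0.2574
GTT,V,0.4059
TAA,*,0.36
TAC,Y,0.48
TAG,*,0.2
TAT,Y,0.52
TCA,S,0.2
TCC,S,0.13
TCG,S,0.1
TCT,S,0.28
TGA,*,0.44
TGC,C,0.4
TGG,W,1
TGT,C,0.6
TTA,L,0.1386
TTC,F,0.49
TTG,L,0.2178
TTT,F,0.51
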