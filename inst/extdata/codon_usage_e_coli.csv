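codon,aa,fraction
AAA,K,0.76
AAC,N,0.55
AAG,K,0.24
AAT,N,0.45
ACA,T,0.1287
ACC,T,0.4356
ACG,T,0.2673
ACT,T,0.1683
AGA,R,0.04
AGC,S,0.28
AGG,R,0.02
AGT,S,0.15
ATA,I,0.07
ATC,I,0.42
ATG,M,1
ATT,I,0.51
CAA,Q,0.35
CAC,H,0.43
CAG,Q,0.65
CAT,H,0.57
CCA,P,0.19
CCC,P,0.13
CCG,P,0.52
CCT,P,0.16
CGA,R,0.06
CGC,R,0.4
CGG,R,0.1
CGT,R,0.38
CTA,L,0.04
CTC,L,0.1
CTG,L,0.5
CTT,L,0.1
GAA,E,0.68
GAC,D,0.37
GAG,E,0.32
GAT,D,0.63
GCA,A,0.21
GCC,A,0.27
GCG,A,0.36
GCT,A,0.16
GGA,G,0.11
GGC,G,0.4
GGG,G,0.15
GGT,G,0.34
GTA,V,0.1531
GTC,V,0.2041
GTG,V,0.3776
GTT,V,0.2653
TAA,*,0.64
TAC,Y,0.43
TAG,*,0.07
TAT,Y,0.57
TCA,S,0.12
TCC,S,0.15
TCG,S,0.15
TCT,S,0.15
TGA,*,0.29
TGC,C,0.55
TGG,W,1
TGT,C,0.45
TTA,L,0.13
TTC,F,0.43
TTG,L,0.13
TTT,F,0.57
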