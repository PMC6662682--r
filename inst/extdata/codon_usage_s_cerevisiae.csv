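codon,aa,fraction
AAA,K,0.58
AAC,N,0.41
AAG,K,0.42
AAT,N,0.59
ACA,T,0.297
ACC,T,0.2178
ACG,T,0.1386
ACT,T,0.3465
AGA,R,0.48
AGC,S,0.11
AGG,R,0.21
AGT,S,0.16
ATA,I,0.2727
ATC,I,0.2626
ATG,M,1
ATT,I,0.4646
CAA,Q,0.69
CAC,H,0.36
CAG,Q,0.31
CAT,H,0.64
CCA,P,0.42
CCC,P,0.15
CCG,P,0.12
CCT,P,0.31
CGA,R,0.07
CGC,R,0.06
CGG,R,0.04
CGT,R,0.14
CTA,L,0.1386
CTC,L,0.0594
CTG,L,0.1089
CTT,L,0.1287
GAA,E,0.7
GAC,D,0.35
GAG,E,0.3
GAT,D,0.65
GCA,A,0.29
GCC,A,0.22
GCG,A,0.11
GCT,A,0.38
GGA,G,0.22
GGC,G,0.19
GGG,G,0.12
GGT,G,0.47
GTA,V,0.21
GTC,V,0.21
GTG,V,0.19
GTT,V,0.39
TAA,*,0.47
TAC,Y,0.44
TAG,*,0.23
TAT,Y,0.56
TCA,S,0.21
TCC,S,0.16
TCG,S,0.1
TCT,S,0.26
TGA,*,0.3
TGC,C,0.37
TGG,W,1
TGT,C,0.63
TTA,L,0.2772
TTC,F,0.41
TTG,L,0.2871
TTT,F,0.59
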