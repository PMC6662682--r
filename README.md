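# gatemut

Design engine for **Golden Gate based point and multi-site saturation
mutagenesis**, with an in-silico assembly validator and Quick Quality
Control (QQC) of pooled-library Sanger chromatograms.

It is written for protein engineers who build site-saturation libraries by
one-pot type IIS restriction–ligation ("Golden Gate") cloning: you supply a
coding sequence and a list of residues to mutate (a specific substitution
such as `D137N`, or a degenerate codon such as `137:NDT`), and the package

* detects internal BsaI/BbsI recognition sites and silently removes them
  ("domestication") using organism-specific codon usage,
* splits the gene into PCR fragments at mutation clusters and selects
  valid, mutually compatible 4 bp junction overhangs,
* emits structured mutagenic primers
  (`padding | recognition site | spacer | 4 bp overhang | mutagenic codons |
  binding region`) with nearest-neighbor melting temperatures balanced to a
  60 °C target,
* simulates the whole workflow (PCR → type IIS digestion →
  overhang-directed ligation) and proves the library reassembles seamlessly,
  in frame, with substitutions only at the requested codons, and
* reads pooled-library `.ab1` chromatograms and reports per-position
  A/C/G/T proportions at every randomized codon, with a total-variation
  score against the intended degeneracy.

Two destination vectors are built in: the universal level 0 cloning vector
**pAGM9121** (BbsI, overhangs `CTCA`/`CGAG`) and the T7 expression vector
**pAGM22082_CRed** (BsaI, overhangs `AATG`/`GCTT`, where `AATG` supplies the
start codon in frame with the vector's N-terminal linker). Designs with
three or fewer fragments are recommended for direct one-step assembly into
the expression vector; larger designs go through per-fragment subcloning
(two-step workflow).

## The core model

Type IIS enzymes (BsaI `GGTCTC(1/5)`, BbsI `GAAGAC(2/6)`) cut outside their
non-palindromic recognition sequence, exposing a user-definable 4 nt
5′ overhang. Of the 4⁴ = 256 possible overhangs, the 16 palindromic ones
self-anneal, leaving **240 usable overhangs** for directional assembly; a
design additionally requires all its overhangs to be pairwise distinct and
mutually non-complementary. Because the recognition sites are released from
correct ligation products, assembly is driven toward completion and the
reconstructed open reading frame is seamless (no scars, no frameshifts).

Randomization sites are encoded between the overhang and the template
binding region of the forward primer of the downstream fragment, so
degenerate codons (NDT = 12 codons, NNK = 32) never sit inside an overhang.
Binding regions are grown from each anchor until the nearest-neighbor
melting temperature (unified parameters, 50 mM monovalent salt, 500 nM
oligo) reaches 60 °C, then the cooler primer of each pair is re-extended
until the pair differs by at most 5 °C.

## Worked example

A 299-codon synthetic gene, NDT saturation at five residues:

```r
library(gatemut)

cds  <- synth_cds(299, seed = 5)                       # 897 nt, site-free
mut  <- mutation_spec(c(137, 143, 147, 232, 234), "saturation", "NDT")
design <- design_mutagenesis(cds, mut)                 # pAGM22082_CRed
design
#> <design_result> 3 fragment(s), 6 primers, vector pAGM22082_CRed (BsaI)
#> <gg_primer> frag 1 forward  TT|GGTCTC|A|AATG|-|AACGGGTGTATGAGGTGTGGACC  Tm 61.2 C
#> <gg_primer> frag 1 reverse  TT|GGTCTC|A|ATCG|-|CGCCTATCATTGGATTCCCCGC  Tm 60.7 C
#> <gg_primer> frag 2 forward  TT|GGTCTC|A|CGAT|CNDTAGTATTCTGTCACGANDTCGCCCGTCGNDT|GGATTACTTAATGTCCGGCGCCTC  Tm 60.4 C
#> <gg_primer> frag 2 reverse  TT|GGTCTC|A|GGAG|-|TTCAAAGGAGCGTGGCTGTTACAC  Tm 60.6 C
#> <gg_primer> frag 3 forward  TT|GGTCTC|A|CTCC|NDTATANDT|GAGTGGTACTCTCGTGACAGCCA  Tm 60.7 C
#> <gg_primer> frag 3 reverse  TT|GGTCTC|A|AAGC|-|TTACCCGATTAGGCACAGTAGCGC  Tm 61.6 C

design$workflow
#> [1] "one_step"

verify_design(cds, mut, design)
#> <assembly_outcome> 902 nt insert, seamless: TRUE, mutated codons: 137, 143, 147, 232, 234
```

Reading the output: the five positions fall into two clusters
({137,143,147} spans 33 nt ≤ 45 nt; {232,234} spans 9 nt), so the gene is
split into **3 fragments** and **6 primers** — few enough for the one-step
workflow. Cluster codons ride on the forward primers of fragments 2 and 3
(`NDT` in the mutagenic insert, wild-type intervening codons carried
verbatim); every binding Tm is within 60–62 °C. The simulated one-pot
reaction reconstructs a 902 nt insert (`AATG` + gene + `GCTT`) whose CDS
differs from the template exactly at the five randomized codons.

`render_protocol(design)` prints the bench protocol (PCR recipe, 15 µl
restriction–ligation with 40 × [37 °C 2 min / 20 °C 5 min] cycling and
80 °C inactivation, transformation notes); `write_design_json()` /
`write_primer_table()` export machine- and spreadsheet-readable reports.
For QQC, `synth_abif_pool()` writes a synthetic pooled chromatogram with
known mixing weights, and `qqc_analysis()` / `render_qqc_report()` recover
per-position base distributions with pie charts and TV scores from any
`.ab1` file. A thin command-line wrapper with subcommands `domesticate`,
`design`, `simulate`, `qqc` and `fixture` lives at `inst/cli/gatemut.R`.

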