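---
title: "Designing Golden Gate saturation-mutagenesis libraries with gatemut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Golden Gate saturation-mutagenesis libraries with gatemut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatemut)
```

## The procedure

Golden Gate cloning exploits type IIS restriction enzymes — here BsaI
(`GGTCTC(1/5)`) and BbsI (`GAAGAC(2/6)`) — which cut double-stranded DNA at
a fixed distance *outside* their non-palindromic recognition sequence,
leaving a 4 nt 5′ overhang whose sequence the designer chooses. Because a
correctly ligated junction no longer contains the recognition site, cutting
and ligation can run in one pot and the reaction is driven toward the
assembled product. 256 − 16 = 240 overhangs are usable (palindromic
overhangs self-anneal); within one design all overhangs must additionally
be pairwise distinct and mutually non-complementary, which `gatemut`
enforces on every plan.

For mutagenesis, the gene is amplified as a small number of PCR fragments
whose primers carry, 5′ to 3′: a short padding, the recognition site, a
spacer, the 4 bp reassembly overhang, the mutagenic codons (absent on
outer and reverse primers) and the template-binding region. Reassembling
the fragments in the destination vector restores the reading frame exactly,
with the new codons at the junctions — this is what `verify_design()`
checks symbolically for every design.

Two vectors are bundled. The level 0 cloning vector pAGM9121 opens with
BbsI and accepts inserts between `CTCA` and `CGAG`; the pET-derived T7
expression vector pAGM22082_CRed opens with BsaI between `AATG` and `GCTT`,
where `AATG` overlaps the start codon (one vector-derived adenine precedes
it, keeping the insert in frame with the vector's N-terminal His/T7
leader). Designs with ≤ 3 fragments are recommended for direct one-step
assembly into the expression vector; larger designs are subcloned fragment
by fragment into pAGM9121 first (two-step), which also supports iterative
strategies (ISM/CASTing) by re-randomizing one fragment at a time.

## Domestication

Internal BsaI/BbsI sites in the gene would be cut during assembly, so they
are removed once, up front, by silent point mutations. `scan_sites()`
searches both strands (the sites are non-palindromic, so orientation
matters); `propose_silent_fix()` enumerates every synonymous single-codon
substitution within the codons overlapped by a hit, discards those that
fail to destroy the site, would create a new site of either enzyme, or use
a rare codon (relative synonymous usage < 0.05 by default), and returns the
substitution with the highest codon usage in the chosen organism
(*E. coli*, *S. cerevisiae* or *A. thaliana*; tables bundled under
`inst/extdata/`, renormalised per amino acid on load). Ties break by
smallest codon index, then alphabetically — a stated convention, since any
tie member is equally valid. If no single-codon substitution works the site
is reported as undomesticatable rather than attempting multi-codon edits.

In the point-mutagenesis workflow, domestication is folded into the same
design pass: each silent fix becomes one more junction, exactly like a
user-requested point mutation (one point mutation plus one internal site
therefore yields three fragments and six primers). For saturation designs
the package instead warns and expects a pre-domesticated gene: the
domestication is needed only once, while the library may be rebuilt many
times.

## Fragmentation and overhang selection

Mutation positions are clustered greedily left to right: a mutation joins
the current cluster if the nucleotide span from the cluster's first mutated
codon through the end of this codon is ≤ `max_cluster_span_nt` (default
45 nt, which keeps full primers within ordinary ~90 nt synthesis limits).
Each cluster becomes one junction, so fragments = clusters + 1.

The junction overhang is the 4 nt template window ending immediately 5′ of
the cluster's first mutated codon. If that window is palindromic, collides
with an overhang already in use (identity or reverse complement), or would
place a genuine enzyme site into the local primer context, the window
shifts up to 6 nt further 5′, carrying the intervening template bases into
the mutagenic insert; failing all shifts is a hard design error. Every
fragment must stay above `min_fragment_len` (default 100 nt, comfortably
gel-resolvable); violations suggest merging clusters.

Mutagenic codons ride on the **forward primer of the downstream fragment**
(one fixed convention keeps reverse primers short); intervening wild-type
codons inside a cluster are carried verbatim. Point-mutation codons are
chosen among the target residue's codons by minimal nucleotide distance
from the wild-type codon (so `L69V`-style single-nucleotide changes fall
out naturally), then by codon usage. The 5′ padding is `TT` and spacers are
`A`-filled — fixed, non-site-forming choices, both configurable.

## Melting temperatures

Binding regions use nearest-neighbor thermodynamics with the unified
parameter set (10 dinucleotide stacks, terminal A/T and G/C initiation
terms, symmetry correction for self-complementary oligos), 50 mM
monovalent salt applied as an entropy correction (0.368 (N−1) ln[Na⁺]) and
500 nM total oligonucleotide (concentration term CT/4, or CT/2 for
self-complementary sequences). Each binding region is the shortest one
reaching the 60 °C target within 12–45 nt; hitting the 45 nt cap below
target flags the primer `low_tm` instead of failing (relevant only for
extreme AT-rich contexts). After initial extension the cooler primer of a
pair is re-extended until the pair's Tms differ by ≤ 5 °C. The
implementation is verified against an independent implementation of the
same parameter set to < 0.1 °C over random 12–40-mers.

## The assembly simulator

`simulate_pcr()` → `digest()` → `ligate()` is a deterministic,
combinatorial oracle: double-stranded DNA is represented by its plus
strand, degenerate bases travel symbolically, and no ligation kinetics,
mismatch ligation or colony statistics are modelled (wet-lab colony counts
are outside what an in-silico model can reproduce). Digestion demands
exactly one inward-facing site per end; ligation demands a unique overhang
chain from the vector's 5′ overhang to its 3′ overhang. `verify_design()`
asserts that the assembled insert equals the mutated template exactly, that
differences from wild type are confined to the specified codons, that no
enzyme site survives in the insert, and — for saturation designs — that
sampled strict expansions of every degenerate codon (seeded, default
seed 17) are in frame with the sampled codon in place.

One deliberate semantic: site checks use **literal (certain) matching**. A
recognition site that only *some* expansions of a degenerate codon would
re-create (e.g. NDT followed by template `CTC` admits `GGTCTC`) cannot be
designed away by shifting overhangs — it is an intrinsic hazard of
saturation libraries, in which those members are re-cut and depleted during
the one-pot reaction. Such primers are flagged (`variant_site_risk`) rather
than rejected; a certain extra site, by contrast, is a hard error. Treating
any possible expansion as fatal would spuriously reject roughly 3% of
random NDT designs while adding no safety for the rest of the library.

## Quick Quality Control

After pooled plasmid preparation and Sanger sequencing, the `.ab1`
chromatogram of the pool is read (`read_abif()`: analyzed channels
DATA9–12, basecalls PBAS, peak locations PLOC, filter-wheel order FWO_).
The read is anchored to the designed insert by the longest exact match of
a non-degenerate reference segment (≥ 20 nt), extended as an ungapped
alignment, and accepted at ≥ 80% identity over ≥ 60 nt — Sanger reads of
plasmid pools have negligible indels, so a full aligner is unnecessary.
Reverse reads are handled by coordinate reflection and base-label
complementation. At each randomized position the A/C/G/T proportions are
the channel intensities at the call's peak scan, normalised to 1, and each
is scored by total-variation distance to the uniform distribution over the
degenerate code's allowed bases (0 = perfect; at most 0.75 against N). The
report is one pie chart per position (red/orange/green/blue for A/C/G/T)
plus a CSV. No pass/fail verdict is attached by default: real pools show
systematic skews (e.g. thymine overrepresentation from primer-mixture
bias), so the TV score is reported for judgement, not thresholded.

## What the synthetic fixtures emulate

All tests run on generated data. `synth_cds()` draws uniform sense codons
between ATG and TAA and resamples until no BsaI/BbsI site remains;
`synth_cds_with_sites()` plants recognition sites at known offsets (these
fixtures deliberately change the encoded protein — they test site removal,
not biology). `synth_abif_pool()` writes a minimal, fully valid ABIF file
in which each channel is proportional to the pool's base frequency at that
position: the known mixing weights of each randomized codon, perturbed by
per-variant log-normal amplification bias (σ = 0.1) — the mechanism that
produces base-ratio skews in real pooled reads. One scan per call, ideal
peaks. What these fixtures do **not** emulate: real chromatogram peak
shapes, dye blobs, mobility shifts, basecall errors and indels, template
secondary-structure effects, or colony-sampling noise in the pool. Passing
tests therefore demonstrate the correctness of the design arithmetic and
the analysis pipeline, not robustness to degraded sequencing data.

Property suites run at moderate sizes chosen to exercise the geometry
thoroughly while keeping the suite fast: 100 random designs (600–1500 nt,
1–5 sites) for end-to-end seamlessness, 200 planted-site fixtures for
domestication, 1000 random oligos for the Tm cross-check.

## Defaults at a glance

| parameter | default | unit | rationale |
|---|---|---|---|
| target Tm | 60 | °C | standard annealing target of the workflow |
| pair ΔTm tolerance | 5 | °C | balanced pairs without over-long primers |
| binding length | 12–45 | nt | synthesis and specificity bounds |
| `max_cluster_span_nt` | 45 | nt | total primer length ≲ 90 nt |
| `min_fragment_len` | 100 | nt | gel-resolvable PCR products |
| overhang shift window | ≤ 6 | nt | local search before declaring failure |
| min codon usage | 0.05 | — | avoid rare codons in silent fixes |
| padding / spacer | `TT` / `A`-fill | — | fixed non-site-forming choices |
| QQC anchor | ≥ 20 | nt | exact seed for ungapped alignment |
| QQC acceptance | ≥ 80% id over ≥ 60 nt | — | pool reads vs. reference |

## Known limitations

* Hairpin/dimer screening and synthesis-cost optimisation are not
  performed; the `variant_site_risk` flag is reported but not scored.
* Overhang choice is template-derived with a local shift search; no
  global optimisation of overhang ligation fidelity is attempted (an
  overhang-fidelity scoring hook is a natural extension).
* Only single-codon silent fixes are considered during domestication.
* Circular templates are not scanned across the origin; inputs are linear
  CDSs from start to stop.
* The ABIF writer/reader covers the tags QQC needs, not the full format.
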