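# Bundled data

## Codon usage tables (`codon_usage_<organism>.csv`)

Relative synonymous codon usage fractions (per amino acid, unitless) for
*Escherichia coli* K-12, *Saccharomyces cerevisiae* and *Arabidopsis
thaliana*, in the style of the Kazusa codon usage database
(https://www.kazusa.or.jp/codon/). Values are rounded genome-wide averages
(two significant digits before per-amino-acid renormalisation); the loader
renormalises each synonym family to sum exactly to 1, so small rounding
residue in the files is harmless. Table version: gatemut-2024.1.

Columns: `codon` (DNA, coding strand), `aa` (single-letter amino acid,
`*` = stop), `fraction` (relative frequency among synonyms).

These tables steer silent-mutation selection during domestication (prefer
frequent codons, reject rare ones); their exact decimals only affect
tie-breaking among near-equivalent synonyms, not design validity.
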