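# tritax

Three-item statement representation of phylogenetic character matrices.

## The problem

Three-taxon statement (3TS) analysis re-expresses a character matrix as a
set of minimal rooted hypotheses of relationship: the statement `A(BC)`
says that taxa B and C are more closely related to each other than either
is to taxon A. Recoding a conventional matrix — binary characters, ordered
(additive) multistate characters, or molecular alignments — into a 3TS
matrix lets standard parsimony and likelihood software analyse
relationships directly, but doing the recoding by hand is hopeless: a
single character scored in *t* taxa can imply thousands of statements.

`tritax` is for systematists who want that conversion as a scriptable,
deterministic tool: CSV in, simplified NEXUS / PHYLIP / CSV out, with
per-statement weights carried alongside.

## The method

For one character, let `n_s` be the number of taxa carrying state *s*
(missing data excluded). `tritax` implements four representations:

- **binary** (Nelson–Platnick): state 0 is plesiomorphic a priori; every
  0-taxon is set against every pair of 1-taxa, giving
  `m·n(n−1)/2` statements for `m` zeros and `n` ones.
- **G** (general): for an unordered multistate character, every observed
  state serves in turn as the outgroup value; the count is
  `Σ_p Σ_{a≠p} n_p·n_a(n_a−1)/2` over ordered state pairs `(p, a)`.
- **W** (fixed outgroup): only the state carried by a designated outgroup
  taxon is plesiomorphic; with binary-notation output this is the **WS**
  form. Count: `n_p·Σ_{a≠p} n_a(n_a−1)/2`.
- **omc** (additive): an ordered character is first decomposed into
  threshold binary columns (Farris coding: one column per observed level
  `v > min`, scoring `state ≥ v`), each enumerated as binary; `-mus`
  keeps only the unique statements per input character.

Weights, computed in exact rational arithmetic:

- **uniform** — every statement weighs 1 (the default);
- **FW** (Nelson–Ladiges fractional weighting) — each statement of a
  binary character weighs `i/s = 2/n`, where `s = n(n−1)(t−n)/2` is the
  total and `i = (n−1)(t−n)` the independent statement count; under G each
  ordered state pair `(p, a)` is treated as a pseudo-binary character, so a
  statement whose pair shares state *a* weighs `2/n_a`;
- **Wt** (fixed-outgroup fraction) — all statements of a W character weigh
  `i_w/s_w` (or `1/s_w` in the alternative variant).

IUPAC ambiguity codes and gaps are treated as missing data by default (the
recommended treatment); an opt-in mode instead averages each statement's
weight over all resolutions of the ambiguous cells. When every character
of a matrix contains ambiguities, weighting is disabled.

## Worked example

A five-taxon unordered character with states `A=0, B=1, C=1, D=2, E=2`:

```sh
$ printf 'A,0\nB,1\nC,1\nD,2\nE,2\n' > toy.csv
$ Rscript inst/scripts/tritax.R toy.csv -ium -ob -og -nex -csv
input: 5 taxa x 1 characters (umc); 1 variable, 1 parsimony-informative
outgroup fixed as: A
statements: 2 total from 1 character(s); representation W, binary notation, uniform weights
wrote toy.3ts.nex
wrote toy.3ts.csv
wrote toy.3ts.weights.tsv
```

`-og` fixes the first taxon (A, state 0) as the outgroup, so only the two
statements `A(BC)` and `A(DE)` survive — B,C share state 1 and D,E share
state 2. The NEXUS matrix holds one column per statement
(out-taxon `0`, in-pair `1`, others `?`):

```
A  00
B  1?
C  1?
D  ?1
E  ?1
```

and the sidecar `toy.3ts.weights.tsv` records, per column, the source
character, the out-taxon, the in-pair and the exact weight. The same
matrix without an outgroup (`-ium -oum -phy`) gives the G representation:
all 6 statements, including `B(DE)`, `C(DE)`, `D(BC)`, `E(BC)`.

The same operations are available as R functions:

```r
library(tritax)
cm <- readCharacterMatrix("toy.csv", dataType = "umc")
buildThreeItemMatrix(cm, outgroup = "A")   # W/WS: 2 statements
buildThreeItemMatrix(cm)                   # G:    6 statements
```

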