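---
title: "Representing character matrices as three-item statements"
author: "tritax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing character matrices as three-item statements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritax)
```

## The model

A rooted phylogenetic hypothesis can be decomposed into its minimal
units: three-item statements (3TS) of the form $A(BC)$ — taxa $B$ and $C$
are more closely related to each other than either is to $A$. `tritax`
converts a conventional character matrix into the complete set of
statements its characters imply, rendered as a new matrix that standard
tree-inference software can analyse. The conversion is purely
combinatorial and deterministic: no randomness, no optimisation, no tree.

For one character, write $n_s$ for the number of taxa carrying state $s$
(taxa with missing states are excluded from that character). The four
representations are:

* **binary** — states 0/1 with 0 plesiomorphic *a priori*. Each of the
  $m$ zero-taxa is set against each of the $\binom{n}{2}$ pairs of
  one-taxa: $m\,n(n-1)/2$ statements.
* **G** (general) — an unordered multistate character carries no
  polarity, so every observed state $p$ serves in turn as the outgroup
  value, paired with every other observed state $a$:
  $\sum_p \sum_{a \neq p} n_p\, n_a (n_a - 1)/2$ statements. On a 0/1
  column G therefore produces both polarities, a strict superset of the
  binary representation.
* **W** (fixed outgroup) — only the state carried by a designated
  outgroup taxon is plesiomorphic; the sum above is restricted to that
  single $p$. With binary-notation output this is the WS form. Each
  character uses the outgroup taxon's own state for that character; if
  the outgroup is missing or ambiguous there, the character is skipped
  with a warning (a fixed polarity simply cannot be read off).
* **omc** (ordered/additive) — the character is first recoded into
  threshold binary columns (one per observed level $v$ above the minimum,
  scoring $\mathrm{state} \ge v$), and each is enumerated as binary. Only
  *observed* levels generate thresholds: an unobserved intermediate level
  would produce a duplicate of an existing column and nothing else.
  Adjacent thresholds can imply the same statement; the
  `mus` option collapses duplicates within one input character (never
  across characters, which remain independent evidence).

Statement order is fixed — characters in input order, then out-taxon
index, then the sorted in-pair — so identical input and configuration
give byte-identical output.

## Notation of the output matrix

Each statement becomes one column scoring exactly three taxa. In
**binary** notation the out-taxon is `0`, the in-pair `1`, everyone else
`?`. In **multistate** notation the original symbols are kept (out-taxon
$p$, in-pair $a$), which for alignments yields an IUPAC-notated matrix
that likelihood software can treat as sequence data. Both notations carry
the same relationships; parsimony treats them alike, model-based methods
need not.

## Weights

Redundancy is intrinsic: of the $s = n(n-1)(t-n)/2$ statements of a
binary character scored in $t$ taxa, only $i = (n-1)(t-n)$ are
independent on a cladogram (any two of $A(BC), A(BD), A(CD)$ imply the
third). Fractional weighting (FW) assigns each statement $i/s = 2/n$.

For the G representation, `tritax` extends FW by treating each ordered
state pair $(p, a)$ as a pseudo-binary character scored in
$t' = n_p + n_a$ taxa with $n' = n_a$ derived: per-pair
$s' = n_p n_a (n_a-1)/2$ and $i' = n_p (n_a - 1)$, so a statement whose
in-pair shares state $a$ weighs $2/n_a$. This per-pair decomposition is a
documented design choice of this package: it degenerates exactly to the
binary closed forms when a single derived state is present, and it
satisfies the two identities any candidate must — the per-character total
$s$ equals the enumeration count, and the weights of a character sum
exactly to its independent count $i$. Both identities are enforced by the
test suite in exact arithmetic.

For the W representation the optional Wt weight is the per-character
fraction $i_w/s_w$, where $s_w$ is the statement total with the outgroup
value fixed; an alternative variant weighs each statement $1/s_w$. Both
are provided (`wtVariant = "fraction"` or `"inverse"`) and neither is
claimed as canonical; the fraction form is the default because it
parallels FW. Fractional weighting of ordered (omc) characters is
deliberately not offered — the additive decomposition makes the
redundancy structure contentious — so omc supports uniform weights only,
and `mus` always implies uniform weights.

All weight arithmetic uses exact rationals (integer numerator/denominator
pairs, reduced by gcd); decimals appear only in serialized output (12
significant digits in the NEXUS `WTSET`, exact fractions in the sidecar
TSV). The quantities involved are small integers bounded by the taxon
count, far below any overflow concern at the enforced size limits.

## Missing data and ambiguity

Gaps (`-`), `?` and empty fields are missing on input, and the default
policy also maps IUPAC ambiguity codes (R, Y, N, …, and B/Z/J/X for
amino acids) to missing — the recommended treatment, since a 3TS derived
from an uncertain state is itself uncertain. The opt-in alternative
(`ambiguity = "average"`) enumerates every resolution of a character's
ambiguous cells and gives each statement the mean of its weights over the
resolutions containing it, scaled by its occurrence fraction
(equivalently: the sum of its per-resolution weights divided by the
number of resolutions). A character with more than 4096 resolutions falls
back to the missing policy with a warning — beyond that point the average
is numerically cheap but scientifically meaningless, as almost no
statement survives in all resolutions. When *every* character of a matrix
contains ambiguities, weighting is disabled outright and all statements
weigh 1.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `representation` | `auto` | `binary`/`omc` follow the declared data type; otherwise `W` if an outgroup is given, else `G` |
| `notation` | `binary` | `multistate` keeps original symbols (IUPAC for alignments) |
| `outgroup` | first taxon (CLI `-og`) | taxon whose states fix polarity under W |
| `weighting` | `uniform` | `fw` (binary/G) or `wt` (W) |
| `mus` | off | unique statements per input character; implies uniform |
| `ambiguity` | `missing` | `average` opts into resolution averaging |
| `maxTaxa`, `maxChars` | 5000, 100000 | input size limits, configurable |

## What the random-matrix generator emulates

`generateMatrix()` draws i.i.d. states per cell (optionally skewed
frequencies), then sprinkles missing cells and ambiguity codes at given
rates. That is exactly what a deterministic recoder needs for testing:
full coverage of alphabets, missing-data patterns and degenerate columns
under a fixed seed. It does *not* emulate real data — no phylogenetic
signal, no among-site rate variation, no alignment error — so passing
tests certify the combinatorics and formats, not the inferential value of
3TS matrices on empirical alignments. The test battery runs the engine
against an independent brute-force oracle (`oracleEnumerate()`, a plain
scan of all $t\binom{t-1}{2}$ taxon triples per character sharing no code
with the engine) on 200 seeded matrices of up to 12 taxa and 30
characters across all data types — sizes chosen so the whole property
suite stays interactive while every admission rule, including ties and
missing-data edge cases, is exercised many times over.

## Numerical and degenerate-input choices

* Constant or otherwise uninformative characters yield empty blocks, not
  errors; a wholly uninformative matrix raises a dedicated
  "no informative statements" condition (CLI exit status 3).
* Ties need no tie-breaks anywhere: statement identity is the
  (out, pair, states) tuple and ordering is lexicographic on indices.
* The CSV dialect is the simplest defensible one — rows are taxa, first
  field the name, no header by default — with flags for header and
  separator. PHYLIP output is relaxed (name + whitespace) by default
  because downstream ML software accepts it; a strict 10-character mode
  is available.
* Weights cannot travel in PHYLIP; they are always written to the
  provenance sidecar TSV instead, which also records each statement's
  source character and taxa.

## Known limitations

* Constant and autapomorphic characters contribute nothing; statements of
  the form $(ABC)$ without an outgroup item are not represented.
* The W-representation convention when an ingroup taxon shares the
  outgroup's state (that taxon then appears as an additional out-item,
  as the enumeration admits every taxon carrying the plesiomorphic
  state) is one of two defensible readings; the package implements the
  inclusive one, and `oracleEnumerate()` encodes the same choice
  independently.
* Ambiguity averaging is exponential in the number of ambiguous cells per
  character, hence the resolution cap.
* No tree inference, support estimation, or reading of NEXUS/FASTA input:
  the package converts matrices, full stop.
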