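---
title: "Computing string assembly indices: model, algorithm, and experiment design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing string assembly indices: model, algorithm, and experiment design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringassembly)
```

## The model

An *object* here is a finite, non-empty string over an arbitrary finite
alphabet.  Objects are built by *recursive compositional joining*: a join
concatenates two available fragments into a new one, and every fragment
built earlier — as well as every single character of the target's alphabet —
remains available for reuse at no further cost.  The **assembly index**
`a(s)` is the minimal number of joins needed to construct `s` this way, and
an **assembly pathway** is a witnessing sequence of joins.  Single
characters are free (`a` of any one-character string is 0), which matches
the convention that a string reachable in `n` doubling steps has length
`l = 2^a`, and the two reference examples:

```{r}
assembly_index("zbzbzc")
assembly_index("zzzbbc")
```

Both strings have the same length, composition, entropy and Huffman code,
but different assembly indices — reuse of the fragment `zb` is worth one
join to the first string and nothing to the second.  That asymmetry is the
entire point of the measure: it scores the *constructive history* a string
admits, not its symbol statistics.

For a whole collection of observations the package computes the ensemble
observable

$$A = \sum_i e^{a_i}\,\frac{n_i - 1}{N},$$

where `n_i` is the copy number of the `i`-th distinguishable object, and
`N` the total count including copies.  An object seen once contributes
nothing: only repeated, independently re-formed objects carry evidence of
selection, and the exponential weight makes complex objects in high copy
number dominate.  `A` uses base *e* as written; no base-switching option is
offered.

## Exact search: the decomposition-set formulation

The implementation rests on an equivalence that is worth stating precisely.
Because a join's product is strictly longer than each operand, any set `S`
of fragments that (i) contains the target and (ii) is *closed* — every
member splits into two parts, each a single character or another member —
can be ordered by length to give a valid pathway with exactly `|S|` joins.
Conversely the products of any pathway form such a set.  Hence

> `a(s)` = minimum size of a closed decomposition set containing `s`.

Two restrictions make the search space finite and small.  First, in a
minimal pathway every product is eventually used inside the target, so it
occurs contiguously in `s`; the search universe is therefore the distinct
substrings of `s` (`candidate_substrings()`).  Second, elementary parts are
free, so only fragments of length at least 2 are ever set members.

The search itself is a depth-first branch-and-bound over partial sets,
implemented in C++:

* **State.**  A bitset of chosen fragments plus the subset still
  *unresolved* (no split selected yet).  The cost of a state is the number
  of chosen fragments; resolving a fragment adds its missing parts as new
  unresolved members.
* **Dominance.**  If an unresolved fragment has a split whose two parts are
  both already available, that split is taken greedily and no alternatives
  are explored: re-pointing any hypothetical solution to the zero-cost
  split leaves it valid and no larger.  Such resolutions do not change the
  available set, so they can all be applied in one pass.
* **Branching.**  Otherwise the fragment with the fewest affordable splits
  is resolved, trying splits in order of how many new fragments they
  require, then left to right.  Split points imposing identical unordered
  part requirements are collapsed beforehand.
* **Pruning.**  (1) Fragment lengths can at most double per new element, so
  a long unresolved fragment whose longest available shorter neighbour is
  `L` needs at least `ceil(log2(len / 2L))` further elements.  (2) Every
  open fragment needs at least one new part drawn from its affordable
  splits; open fragments whose candidate-part sets are pairwise disjoint
  need pairwise distinct new parts, giving a hitting-set style count bound.
  (3) When exactly one more element may be added, the remaining problem is
  solved directly by set intersection instead of recursion.  (4) A table of
  visited states is kept; a state's optimal completion does not depend on
  how it was reached, so revisits are cut.
* **Determinism.**  The initial upper bound comes from the greedy
  construction below, branching follows a fixed canonical order, and the
  witness is emitted with members sorted by length, so equal inputs always
  produce identical results and pathways.

The decision problem is NP-complete, so exponential worst-case time is
expected; on 16-character strings over three letters the search needs a few
tens of milliseconds.  The `budget` argument caps the search depth and the
`max_nodes` argument caps the explored node count; when either is exhausted
the result reports the proven interval `[lower, upper]` with
`exact = FALSE` — an honest bound pair, never a guess.

An earlier design iterated deepening over forward join sequences (pools of
built fragments).  It was correct but orders of magnitude slower on the
permutation experiment; the decomposition-set formulation explores the same
optimum with far stronger pruning, and the forward view survives as the
independent brute-force oracle (`brute_force_assembly_index()`), a plain
breadth-first search over pools used throughout the test suite.

## Bounds

`assembly_lower_bound()` is the doubling bound `ceil(log2 l)`.
`greedy_upper_bound()` builds a real pathway: it finds the longest
substring with two non-overlapping occurrences (ties: leftmost, then
lexicographic), builds it recursively, then assembles the target left to
right always consuming the longest available matching fragment.  Building
*one* repeated fragment per recursion level matters: constructing every
repeated substring up front wastes joins on fragments the final assembly
never uses.  The greedy bound is tight on doubling-friendly inputs
(`aaaaaa` gets 3) and within one or two joins on the experiment strings.

## Baselines

*Shannon entropy* is the character-frequency entropy in bits per symbol —
a function of composition alone.

*Huffman coding* is included with an exactly specified tie-breaking
convention, because Huffman trees are degenerate and the reference code
maps are only reproducible bit for bit under a fixed rule: node priority is
`(weight, creation order)` with leaves created first in first-appearance
order; on a merge the heavier child takes bit `1`, ties going to the leaf
or earlier-created node.  This yields `z -> 1, b -> 01, c -> 00` and the
encodings `101101100` / `111010100` for the two example strings.  A
single-symbol string gets code `"0"`.

*LZW* starts its dictionary from the distinct input characters in
first-appearance order (a full byte alphabet is available via the
`alphabet` argument).  Emitted code streams are reported under three size
policies, because a byte count for LZW is convention-dependent:
`code_count` (number of codes), `fixed12_bytes` (12 bits per code), and
`minwidth_bytes` (all codes at the minimal fixed width addressing the final
dictionary).  `minwidth_bytes` is the package default for "compressed size
in bytes"; the experiments report all three so conclusions are not hostage
to the convention.  The minimal-width formula is applied as stated even in
the degenerate one-entry-dictionary case, where it gives zero bytes.

## Experiments

`scaling_table()` contrasts the two growth laws: `n` LZW dictionary steps
reach at most the triangular length `n(n+1)/2`, while `n` joins reach
`2^n`.  With `validate_upto = 6` the closed forms are recomputed by running
the actual compressor and the actual search on unary strings — the table is
not allowed to assert formulas the code does not reproduce.

`correlation_experiment()` is the fixed-composition study: `k` uniform
random rearrangements of `aaaaaabbbbbbcccc` (16 characters; 1,681,680
distinct permutations, so 10,000 draws essentially never repeat), exact
assembly index and LZW size per string, Pearson correlation per size
policy, and the histogram and moments of the difference `lzw − a`.
Holding length and composition fixed is what makes the correlation
meaningful: across mixed lengths both measures grow with size and any
correlation is inflated by that shared trend.  The default protocol is
sampling with `k = 10,000`; full enumeration of all permutations is
available via `full = TRUE` for small bases.  Both the ratio `a / size`
and the difference are reported, and exact indices are memoized per
distinct string.  Sampling uses one explicit seed; the caller's RNG state
is saved and restored around every randomised helper.

Problem sizes used by the shipped tests and the acceptance script: the
correlation study runs at `k = 10,000` per seed; oracle equivalence is
exhaustive over all 510 binary strings up to length 8 and sampled over
three- and four-letter alphabets; unary/addition-chain equality is checked
for all lengths up to 32; round-trip checks use 1,000 random strings.

## What the generator emulates — and what it does not

`generate_fixtures()` and `sample_permutations()` produce uniform random
strings of fixed composition or fixed length.  They emulate the null
condition of the comparison study: objects with identical size and symbol
statistics whose constructive structure varies freely.  They do not emulate
real molecular data — no bond constraints, no measurement noise, no copy
numbers from instrument counts — so passing tests demonstrate the formal
properties of the measures, not laboratory biosignature performance.  The
empirical high-copy-number threshold for living samples is out of scope
here for exactly that reason.

## Numerical and design choices

* Identity of objects is exact string equality; the ensemble builder
  counts copies by equality and rejects duplicated values in direct
  construction.
* `count_permutations()` multiplies binomial coefficients instead of
  dividing factorials, staying exact in double precision far beyond the
  sizes that are enumerable anyway.
* Empty strings are rejected everywhere: assembly objects are non-empty
  and breakable.
* `pearson()` treats zero variance as an error rather than returning `NA`,
  so degenerate experiment configurations fail loudly.
* FASTA input is parsed by Biostrings, uppercased, whitespace-stripped,
  and not alphabet-validated (the index is alphabet-agnostic); a sequence
  line before the first header is an error with its line number.
* The CLI is a thin Rscript over exported functions; all subcommands exit
  non-zero on error.

## Known limitations

Exact search beyond a few tens of characters can become expensive — the
problem is NP-complete and no bound battery changes that; use `budget` or
`max_nodes` to obtain certified intervals instead.  The greedy bound has no
approximation guarantee.  `addition_chain_min()` is an independent
exhaustive solver intended for `l` up to about 64; for larger unary inputs
use `assembly_index()` itself, whose pruning handles power-of-two lengths
up to at least 2^10 instantly but can slow near adversarial lengths.
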