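# stringassembly

Exact assembly indices, assembly pathways, and the ensemble Assembly
observable for strings, together with the compression-based complexity
measures they are commonly compared against.

## The problem

Assembly theory quantifies how much constructive history an object
carries.  For strings, the **assembly index** `a(s)` is the minimal number
of joining operations needed to build `s` from its single characters,
where each join concatenates two available fragments and every fragment
built earlier may be reused at no further cost.  Two strings of identical
length, composition, entropy and Huffman code can have different indices —
the index sees structure that symbol statistics cannot.  Over an observed
collection of objects the theory combines indices with copy numbers into
the ensemble observable

```
A = Σ_i e^(a_i) · (n_i − 1) / N
```

with `n_i` the copy number of the `i`-th distinguishable object and `N`
the total count including copies: objects seen once contribute nothing,
while complex objects in high copy number dominate.

The package is for anyone who wants these quantities to be *computed
rather than asserted*: exact indices with verifiable minimal pathways, an
independent brute-force oracle, the Huffman/LZW/entropy baselines under
deterministic conventions, and the comparison experiments (growth-law
scaling and the fixed-composition correlation study) as reproducible
functions.

## Why substrings suffice (soundness of the search space)

The exact search only ever considers contiguous substrings of the target.
This is sound: take a minimal pathway and remove any join whose product is
never used later — minimality means no such join exists, so every product
is an operand of a later join, and by induction every product ends up as a
contiguous block of the final string.  Hence every fragment on some
minimal pathway occurs contiguously in the target, and restricting the
search to `candidate_substrings(s)` loses no optimum.  On top of this the
implementation uses the equivalence between pathways and *closed
decomposition sets* (every member splits into two members or single
characters; products are strictly longer than operands, so any closed set
orders into a pathway by length) and runs a branch-and-bound over such
sets in C++.  See the methods vignette for the algorithm and its pruning
rules.

## Worked example

```r
library(stringassembly)

r <- assembly_index("zbzbzc")
r
#> Assembly index of "zbzbzc": 4 (exact)
r$pathway
#> Assembly pathway for "zbzbzc" (4 join steps)
#>    1. z + b -> zb
#>    2. zb + zb -> zbzb
#>    3. zbzb + z -> zbzbz
#>    4. zbzbz + c -> zbzbzc

assembly_index("zzzbbc")
#> Assembly index of "zzzbbc": 5 (exact)
```

`zbzbzc` needs 4 joins because the fragment `zb` can be built once and
reused; its anagram `zzzbbc` offers no such reuse and needs 5.  Huffman
coding cannot tell them apart — same frequencies, same tree, same code:

```r
huffman_code("zbzbzc")$code
#>    z    b    c
#>  "1" "01" "00"
huffman_encode("zbzbzc")
#> [1] "101101100"
huffman_encode("zzzbbc")
#> [1] "111010100"
```

Copy numbers turn indices into the Assembly observable:

```r
e <- ensemble_from_observations(c(rep("zbzbzc", 10), rep("zzzbbc", 2), "abcdef"))
e
#> Assembly ensemble: 3 distinguishable objects, N = 13 total
#>    value copy_number index
#> 1 zbzbzc          10     4
#> 2 zzzbbc           2     5
#> 3 abcdef           1     5
#> Assembly A = 49.21512
```

The ten copies of the index-4 string carry almost all of `A`; the
singleton contributes exactly zero.  And the growth-law gap that separates
assembly from dictionary compression:

```r
scaling_table(6)
#>   steps lzw_reachable_length assembly_reachable_length
#> 1     1                    1                         2
#> 2     2                    3                         4
#> 3     3                    6                         8
#> 4     4                   10                        16
#> 5     5                   15                        32
#> 6     6                   21                        64
```

`n` LZW steps reach a single-letter string of length `n(n+1)/2`; `n` joins
reach `2^n`.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","stringassembly.R",package="stringassembly"))')" \
    index strings.txt --output json
```

Subcommands: `index`, `ensemble`, `baselines entropy|huffman|lzw`,
`scaling`, `permtest`, `fixtures`.

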