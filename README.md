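# cabin — cellular-automaton binning of metagenomic reads

`cabin` is an R package for *unsupervised binning* of metagenomic
sequencing reads: grouping reads by their species of origin using only
sequence composition, with no reference database, no assembly, and no
preset number of clusters.  It is aimed at researchers studying
taxonomy-independent binning methods and at anyone who needs a fully
reproducible, self-contained binning benchmark (the package ships its
own labelled read simulator).

## The method

Each read is summarised by its **k-mer spectrum** — the frequency
vector of all `4^k` words of length `k` (default `k = 5`, so 1024
dimensions) — and the dissimilarity between reads is the Euclidean
distance between spectra, `d(x_i, x_j) = ‖x⃗_i − x⃗_j‖`.

The clustering engine is a **one-dimensional cellular automaton**: the
`N` reads are scattered over a circular lattice of `N` cells
(`c_{N+1} = c_1`), and for ranges `r = 3 … R` the transition rule `φ_r`
at cell `i` swaps the reads at cells `i+1` and `i+r−1` whenever
`d(x_i, x_{i+1}) > d(x_i, x_{i+r−1})`, i.e. whenever the read next door
is compositionally farther than the one at range `r−1`.  Iterating
these local swap rules sorts similar reads into contiguous arcs while
using only linear memory, and stops at a fixed point where no rule can
fire.

The converged chain is then cut into bins by scanning its **chainmap**
(the distances between consecutive cells): a read starts a new cluster
when the gap behind it is large both globally and relative to the
running statistics of the current cluster, the distances fall off
monotonically across the gap, and the current cluster already spans at
least 30 cells.  Against truth labels the package reports the standard
benchmark metrics: **precision** `Σ_i max_j R_ij / Σ_ij R_ij` over the
confusion matrix `R_ij`, and the per-species **false-positive rate**
over the clusters called as each species.

See the vignette (`vignettes/ca-binning-methods.Rmd`) for the full
model, the design decisions, and the known limitations.

## Worked example

Simulate a three-species mixture (abundance ratio 1:3:9, 1%
substitution errors) and bin it:

```r
library(cabin)

sim <- simulate_metagenome(n_reads = 600, seed = 42)
sim
#> simulated reads: 600 reads, 3 species
#> per-species counts: sp1=53, sp2=122, sp3=425

res <- bin_reads(sim$reads, seed = 42, truth = sim$truth)
res
#> 1D-CA binning of 600 reads  (k = 5, R = 98, seed = 42)
#>   converged after 12 iterations
#>   clusters (K): 10; sizes: 60, 35, 46, 38, 39, 31, 45, 32, 37, 237
#>   precision: 0.8083
#>   FP rates: sp2=0.4852, sp3=0.0000, sp1=    NA
```

The automaton converged to a fixed point after 12 iterations and the
boundary detector cut the chain into 10 clusters.  Precision 0.81 means
81% of reads lie in the majority species of their cluster.  The
dominant species (sp3) is recovered with a false-positive rate of 0 —
its clusters contain no foreign reads — while the clusters called as
sp2 also captured reads of the rarest species (FP rate 0.49), and sp1
is never the majority of any cluster (`NA`): under-detection of
boundaries folds rare species into their neighbours, the method's
characteristic error mode.  Over-segmentation of one species across
several clusters (visible in the many ~40-cell clusters) does not harm
precision.

Per-read assignments are in `res$cluster`; `write_binning(res, dir)`
exports assignment, chainmap, and evaluation tables as TSV.

A command-line front end with `simulate`, `bin`, and `eval` subcommands
is installed at `system.file("scripts", "cabin", package = "cabin")`.

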