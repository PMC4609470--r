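# estpoly

Comparative EST polymorphism analysis between two transcript libraries.

`estpoly` quantifies sequence divergence between two expressed-sequence-tag
(EST) collections — for example an introgression or somatic-hybrid line
against its parent cultivar — from plain FASTA input. It cleans single-pass
reads, clusters each library into unigenes (contigs + singletons), matches
the two unigene sets by filtered local alignment, and calls and summarises
three classes of polymorphism:

- **directional SNPs** (subject→query patterns, e.g. `G->A`; transition /
  transversion spectra over the 12 substitution patterns),
- **small indels** lying within an alignment (one event per maximal gap
  run; per-length 1–10 nt spectra and insertion:deletion ratios),
- **large indels** that split a matched pair into two alignments
  (23–574 nt scale), classified mechanistically by their flanking sequence
  into *identical flanks*, *boundary repeats* (replication-slippage
  signature: the gained/lost segment duplicates a 1–51 nt motif at its
  breakpoint) and *modified flanks*.

Frequencies are reported per 1000 nt of matched sequence, following the
standard definitions of this literature: identity is computed over
alignment columns (gaps included), matching keeps one best subject per
query at ≥ 96 % identity, E ≤ 1e-10, HSP ≥ 33 columns, and the frequency
denominator is the total matched column count.

The core quantities, for SNP count S, small-indel count I and matched
length M (columns):

    SNP/kb  = 1000 · S / M         (split into transitions A↔G, C↔T
    indel/kb = 1000 · I / M         and transversions, and into the
                                    12 directional patterns)

plus the per-bin insertion:deletion ratio r(ℓ) = n_ins(ℓ)/n_del(ℓ) with its
Pearson correlation against indel length ℓ, positional GC profiles over the
ten nucleotides flanking each indel, and boundary-repeat motif detection at
indel breakpoints.

A seeded divergence simulator (`simulate_pair()`) generates library pairs
with exact ground truth (substitutions, indels, repeat-mediated events,
per-branch edit lists closed under liftover), so the whole pipeline is
testable offline; `recovery_report()` compares planted and estimated
values.

## Worked example

Simulate a 60-unigene library pair under the default divergence conditions
and run the full pipeline (cleaning is configured not to truncate the
simulated 700–1000 nt unigenes):

```r
library(estpoly)

sim <- simulate_pair(synth_params(n_unigenes = 60, seed = 4))
res <- run_pipeline(sim$lib_a, sim$lib_b,
                    pipeline_config(max_prefix_len = 2000))
res
#> <est_pipeline>
#> <est_match> 60/60 queries matched (67 HSPs); coverage 96.16%
#> <polymorphism_summary> 51681 columns matched
#>   SNPs: 575 (11.126/kb; transitions 6.424, transversions 4.702)
#>   small indels: 62 (1.200/kb; insertions 0.774, deletions 0.426)
```

All 60 simulated homolog pairs matched; 51,681 alignment columns form the
frequency denominator. The 575 called SNPs correspond to 11.13 per 1000 nt
against a planted pairwise rate of 11.33/kb, split 6.42 transition / 4.70
transversion; 62 small indels give 1.20/kb. Result objects are tidyverse
citizens — `tidy()` returns the underlying tables, `glance()` one-row
summaries, `autoplot()` the standard displays:

```r
head(tidy(res$summary), 4)
#> # A tibble: 4 × 4
#>   statistic group          n per_kb
#>   <chr>     <chr>      <int>  <dbl>
#> 1 snp_A->G  transition    81   1.57
#> 2 snp_C->T  transition    98   1.90
#> 3 snp_G->A  transition    85   1.64
#> 4 snp_T->C  transition    68   1.32

autoplot(res$spectrum_small)   # indel length vs insertion/deletion ratio
autoplot(res$flanks)           # flanking GC profile
```

Recovery against the simulator's truth table:

```r
dplyr::select(recovery_report(sim, res),
              parameter, planted, estimated, relative_error)
#>                  parameter planted estimated relative_error
#> 1                      snp     582       575          0.012
#> 2               transition     336       332          0.012
#> 3             transversion     246       243          0.012
#> 4          small_insertion      40        40          0.000
#> 5           small_deletion      25        22          0.120
#> 6              small_indel      65        62          0.046
#> 7              large_indel       7         7          0.000
#> ...
```

At 60 unigenes the rarer event classes carry visible sampling noise (25
planted deletions); at the validation scale of 500 unigenes every rate is
recovered within 5 % (see below). The missing events sit in the two blind
spots every alignment-based caller shares — events within ~10 nt of a
sequence end, and opposite-polarity events a few bases apart — both
discussed in the methods vignette (`vignettes/estpoly-methods.Rmd`).

Real data enter the same way: `read_fasta("libA.fasta")` /
`read_fasta("libB.fasta")` in place of the simulated tibbles, and
`functional_bins()` accepts a unigene→category TSV for Table-style
per-function summaries. A thin command-line wrapper is installed at
`exec/estpoly` (subcommands `simulate`, `clean`, `cluster`, `match`,
`callvar`, `stats`, `classify`, `all`).

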