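# tegenome

Genome-context analytics for repeat-rich fungal genomes. The package asks,
and answers quantitatively, the questions raised by TE-inflated genomes such
as those of ectomycorrhizal mushrooms (e.g. *Tricholoma matsutake*, whose
assembly is roughly half transposable elements):

* **TE context** — which genes have transposable elements on *both* flanks
  (a repeat > 400 bp intersecting a 1 kbp window on each side of the gene
  span), and are those genes transcriptionally silenced more often than the
  background? The association is tested with a Fisher exact 2×2 test, and
  paralog/ortholog "rescue" evidence distinguishes silenced real genes from
  annotation artifacts.
* **RIP bias** — do repeat families carry repeat-induced point mutation
  signatures: a pooled transition/transversion ratio > 2 together with more
  than one third of copies showing a dominant C→T dinucleotide context
  (CpA/CpC/CpG/CpT, reverse-strand G→A events mapped to the complementary
  context)?
* **Expression patterns** — from a gene × stage FPKM table (hyphae,
  primordia, fruiting body), classify every gene into one of seven patterns
  (H, P, F, HP, PF, HF, NS) using strict |log₂FC| > 1 thresholds on
  pseudocount fold changes, call expressed genes (> 1 FPKM), transition
  up/down sets, the constitutive top-k set, and Fisher-exact GO-slim
  enrichment.
* **Evidence voting** — integrate multi-tool verdicts: secretome ≥ 3-of-4
  voting with a TM/ER/GPI exclusion cascade (single N-terminal helix ≤ 70 aa
  exempt), small secreted proteins (< 300 aa; cysteine-rich > 3% Cys),
  CAZyme ≥ 2-of-3 family agreement, and RNA-seq/Pfam/ortholog gene-support
  flags.
* **Genome statistics** — N50, GC partitioned into coding/non-coding space,
  gene density, percent coding, complete-CDS filtering, intergenic
  distances.

Every analysis is exercisable on synthetic data with planted ground truth
(`simulate_all()`), and readers/writers cover FASTA, GFF3, RepeatMasker
`.out`, BED-like repeat TSV, FPKM/vote TSV tables and JSON reports. See the
methods vignette (`vignettes/tegenome-methods.Rmd`) for the model decisions
and their rationale.

## Worked example

Simulate the default world — 5 scaffolds × 1 Mbp, 500 genes, 20% planted
TE-surrounded, silencing probability 0.832 given TE context vs 0.32
background, 20 CpG-RIP'd repeat families — then run the analyses:

```r
library(tegenome)

cfg <- simulation_config(seed = 20)
sim <- simulate_all(cfg)

te <- classify_te_surrounded(sim$genes, sim$repeats)
length(te)
#> [1] 100
suppression_association(te, sim$expression)[
  c("n_silent_among", "pct_silent_among", "background_silent_pct", "fisher_p")]
#> $n_silent_among
#> [1] 84
#> $pct_silent_among
#> [1] 84
#> $background_silent_pct
#> [1] 32.8
#> $fisher_p
#> [1] 5.512652e-21
```

All 100 planted TE-surrounded genes are detected; 84% of them are silent
versus 32.8% of the background (both within binomial error of the planted
probabilities), and the 2×2 association is decisive (p ≈ 5.5e-21).

```r
calls <- lapply(sim$families, function(f)
  classify_rip_family(family_rip_statistics(f$family)))
genome_rip_summary(calls)
#> $n_families
#> [1] 20
#> $n_rip
#> [1] 17
#> $context_histogram
#> $context_histogram$CpG
#> [1] 17
#> $modal_context
#> [1] "CpG"
```

At the generator's moderate default mutation rate, 17 of 20 families clear
both RIP rules, all with the planted CpG dominant context (the three misses
sit at the ti/tv > 2 boundary; see the vignette on signal strength).

```r
table(classify_pattern(sim$expression)$pattern)
#>   F   H  HF  HP  NS   P  PF
#>  53  58  22  29 276  39  23

pipe <- secretome_pipeline(sim$votes, sim$topology)
lengths(pipe[c("secreted", "ssp", "cysteine_rich")])
#>      secreted           ssp cysteine_rich
#>            40            20             7
```

The seven patterns partition all 500 genes, and the noise-free vote tables
are recovered exactly (40 planted secreted, 20 SSPs, 7 cysteine-rich).

## Command line

```sh
Rscript inst/cli/tegenome simulate --seed 3 --out-dir sim/
Rscript inst/cli/tegenome stats --genome sim/genome.fa --gff3 sim/genes.gff3 --out-dir out/
Rscript inst/cli/tegenome te-context --gff3 sim/genes.gff3 \
    --repeats sim/repeats.tsv --fpkm sim/fpkm.tsv --out-dir out/
Rscript inst/cli/tegenome rip --families sim/families --out-dir out/
Rscript inst/cli/tegenome expression --fpkm sim/fpkm.tsv --out-dir out/
Rscript inst/cli/tegenome vote --secretion sim/votes/secretion.tsv \
    --topology sim/votes/topology.tsv --cazyme sim/votes/cazyme.tsv --out-dir out/
```

Thresholds are `key = value` entries in an optional `--config` file
(defaults are the published values, e.g. `window = 1000`,
`min_te_len = 400`, `fpkm_threshold = 1`); every JSON report embeds the
configuration it was produced with.

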