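# circkit

Circular RNAs (circRNAs) are covalently closed transcripts formed when a
downstream splice donor joins an upstream splice acceptor — a back-splicing
event whose tell-tale signature is the back-splice junction (BSJ), an
exon–exon junction absent from the linear host transcript. A dozen detection
tools call circRNAs from BSJ-spanning reads, each with its own output format,
coordinate conventions, sensitivity and false-positive profile. What comes
*after* detection is the hard part this package addresses: harmonizing the
predictions of several tools into one junction table and carrying that table
through expression, conservation, sequence and biogenesis analyses.

circkit is aimed at transcriptomics researchers who already ran one or more
of MapSplice2, NCLscan, CircMarker, CircExplorer2, KNIFE or UROBORUS and want
a reproducible downstream workflow:

* **import & merge** — table-driven adapters normalize each tool's dialect to
  canonical 1-based, inclusive, transcription-ordered coordinates; one record
  per unique junction `gene|strand|chrom|startUpBSE|endDownBSE`, with per
  (tool, sample) read counts and the number of supporting tools;
* **antisense flagging** — predictions whose strand contradicts the annotated
  gene while both coordinates still sit on exon boundaries are flagged and
  excluded by default;
* **prevalence filter** — a junction survives when at least one condition has
  `min_samples` samples with at least `min_count` reads (defaults 3 and 5);
* **differential expression** — a self-contained negative-binomial Wald test:
  median-of-ratios size factors s_j, per-junction moment dispersions
  alpha shrunk toward the trimmed-mean dispersion, log2 fold change
  log2((mu_B + 0.5)/(mu_A + 0.5)) with delta-method standard error under
  Var(K) = mu + alpha * mu^2, two-sided normal p and Benjamini–Hochberg
  adjustment; significance defaults |log2FC| >= 1 and padj <= 0.05;
* **liftover** — a UCSC chain parser and exact point lifting of both junction
  coordinates (highest-scoring chain wins; gap positions are unmapped);
* **sequences** — internal circRNA sequences in circular topology,
  read-through junction sequences, and flanking regions (full introns,
  200 nt intron + 10 nt exon biogenesis windows, or the back-spliced exons);
* **screens** — IUPAC motif scanning with fold enrichment vs a background set
  (rate per kb + Fisher exact), k-mer over-representation, junction-aware
  miRNA seed sites (seed = mature positions 2–8; accepted when total matches
  >= 6 with >= 5 Watson–Crick and <= 1 G:U wobble), GWAS SNPs and inverted
  Alu repeats in the flanking introns;
* **random backgrounds** — exon-boundary-true random BSJs drawn from the
  annotation, plus a deterministic synthetic fixture generator (mini genome,
  GTF, all six tool dialects, motif/miRNA/SNP/repeat/chain files with a
  ground-truth manifest).

## Worked example

Everything below runs on the shipped synthetic fixture, so it is fully
reproducible:

```r
library(circkit)
library(dplyr)

fx <- tempfile(); build_fixture(fixture_spec(seed = 7), fx)
out <- tempfile()
res <- run_pipeline(file.path(fx, "config.yml"), out)

glance(res$de)
#> # A tibble: 1 × 6
#>   contrast           n_tested n_significant lfc_cut alpha_cut median_dispersion
#>   <chr>                 <int>         <int>   <dbl>     <dbl>             <dbl>
#> 1 disease vs control       20             3       1      0.05             0.161

nrow(res$merged)        # 34 junctions merged across 6 tools x 6 samples
sum(res$merged$antisense)  # 2 antisense predictions flagged and excluded
nrow(res$filtered)      # 20 survive the >=5-reads-in->=3-samples filter
mean(res$lift$lifted)   # 1: every filtered BSJ lifts through the shift chain

res$mirna_sites |> filter(spans_junction) |> select(circ_id, mirna_id, pos, wc)
#> # A tibble: 1 × 4
#>   circ_id                   mirna_id    pos    wc
#>   <chr>                     <chr>     <int> <int>
#> 1 gene05|+|chrA|10182|10330 mir-fix-2   147     7
```

The merged table has 34 rows because the six tools agree on 20 true
junctions, each tool contributes 2 private low-count decoys (12), and two
antisense artifacts are reported by two tools; the filter then removes every
decoy. The junction-spanning miRNA site is found only because internal
sequences are scanned in circular topology — a linear scan of the same string
misses it. Per-junction tables come from `tidy(res$de)`; `autoplot(res$de)`
draws the volcano plot, and `autoplot()` on the motif enrichment table plots
fold enrichments.

The same stages are available from a shell via the installed script (add the
package's `exec/` directory to your PATH, or call it by its installed path):

```sh
circkit=$(Rscript -e 'cat(system.file("exec", "circkit", package = "circkit"))')
$circkit fixture --seed 7 --out fx/
$circkit run --config fx/config.yml --out out/
```

Subcommands: `fixture`, `run`, `import`, `annotate`, `filter`, `de`,
`liftover`, `random-bsj`, `seqs`, `motifs`, `mirna`, `regions`.

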