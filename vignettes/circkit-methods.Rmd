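---
title: "circkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, and where genuinely open design questions were settled. It states no
empirical result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The junction as the unit of analysis

A circRNA is identified by its back-splice junction (BSJ): the covalent join
between the last transcribed base of a downstream back-spliced exon and the
first transcribed base of an upstream one. circkit's canonical record stores
both coordinates 1-based, inclusive, **in transcription order** —
`startUpBSE <= endDownBSE` on `+` genes and the reverse on `-` genes — because
every downstream operation (annotation against a GTF, sequence extraction,
window construction) reasons in the transcript's 5'→3' frame. Each detection
tool declares its own coordinate base (0 or 1) and end convention (inclusive
or half-open) in a `tool_dialect`, and the importer normalizes on entry; the
six shipped dialects are best-effort defaults, deliberately overridable,
since published tool formats drift between versions.

Merging keys on the full identity tuple (gene, strand, chrom, startUpBSE,
endDownBSE). When two tools attribute the same coordinates to different gene
symbols, both records are kept and a warning is raised: collapsing them would
silently discard one attribution, and the ambiguity is real in dense loci.
Zero-count rows are retained at import — filtering is a separate, explicit
stage, so "a tool reported this junction with zero supporting reads in this
sample" remains distinguishable from "a tool never reported it".

**Antisense flagging.** A prediction whose strand contradicts the annotated
strand of its gene, while both coordinates still fall on exon boundaries of
that gene, is most parsimoniously a strand-assignment artifact (or an
unannotated antisense transcript); such records are flagged `antisense` and
excluded downstream by default, with an override for users who want to keep
them. A strand conflict *without* exon-boundary support is flagged
`unannotated` instead — there is no evidence tying it to the gene at all.

## Annotation and the exact-boundary rule

`annotate_circs()` requires both BSJ coordinates to coincide exactly with
annotated exon edges of a single transcript (tolerance configurable, default
0 nt). The supported detection tools are annotation-guided, so their
coordinates are exon edges by construction; a non-zero tolerance mostly
admits mapping noise. When several transcripts qualify, the one with the most
exons wins, ties broken by genomic span and then transcript id — an arbitrary
but deterministic rule, fixed so that reruns and liftovers are reproducible.
Whether both coordinates must match the *same* transcript is an open question
in the field's tooling; requiring it is the stricter choice and is what makes
the internal exon chain well-defined.

## The prevalence filter and cross-tool counts

Tools report overlapping evidence for the same junction, so per-sample counts
are aggregated across tools with `max` by default — the conservative choice
against double-counting the same BSJ-spanning reads; `sum` and single-tool
modes exist for users who trust one caller. The filter itself retains a
junction when **some** condition has at least `min_samples` samples with at
least `min_count` reads (defaults 5 reads in 3 samples), evaluated
per-condition so a junction expressed in only one group survives.

## Negative-binomial Wald test

Most circRNA workflows delegate differential testing to DESeq2/edgeR; this
package instead ships a self-contained NB pipeline so the statistical path is
fully inspectable and testable (DESeq2 appears only as an independent
cross-check in the test suite):

* **Size factors**: median-of-ratios over zero-free rows, rescaled to
  geometric mean 1; total-count fallback (with a warning) when no zero-free
  row exists.
* **Dispersion**: per-junction method of moments
  `alpha_hat = max(0, (s2 - mu) / mu^2)` on normalized counts, with `s2` the
  df-weighted pooled within-condition variance. At 2–3 samples per group
  these moments are extremely noisy (and the truncation at 0 biases
  individual estimates down), so each is moderated toward the 10% trimmed
  mean across junctions, retaining weight 0.3 on the per-junction moment.
  The moderation strength was fixed by requiring the downstream Wald test to
  hold its nominal size in null simulations at n = 3 per group (the weaker
  alternative — 70% weight on the noisy per-junction moment — measurably
  inflates the type-I error to ~0.09 at nominal 0.05).
* **Test**: log2FC = log2((mu_B + 0.5)/(mu_A + 0.5)) — the 0.5 pseudocount
  enters the point estimate only, never a likelihood — with the delta-method
  standard error of a NB group mean, two-sided normal p, and BH adjustment.
  Significance defaults to |log2FC| >= 1 and padj <= 0.05.

**Known limitation.** With 3 samples per group and dispersion ~0.2, the
standard error of a log2 fold change is ~0.53, so the power to call a true
|log2FC| = 2 effect at BH 0.05 plus the |log2FC| >= 1 gate is ~0.75 — for
*any* NB Wald test, including DESeq2 on the same matrices (the test suite
verifies both statements by simulation). Sensitivity expectations at such
designs should be set accordingly.

## Liftover

The UCSC chain parser verifies the block-sum invariants on load and names the
offending chain in errors. Points lift only when they fall inside an aligned
block; positions in dt/dq gaps are unmapped *values*, not errors. Overlapping
chains resolve by descending score, mirroring liftOver's ordering; there is
no fractional "minMatch" mapping because the unit of interest is a single
junction base. A BSJ lifts when both ends map to the same destination
chromosome with the same orientation; mixed orientations are reported as
`strand_conflict`, different chromosomes as `split`.

## Sequences in circular topology

Internal sequences concatenate the internal exons in transcription order
(reverse-complemented per exon on `-` genes) and are flagged circular. All
scanning respects that flag by extending the sequence with its first
`k - 1` bases, so a k-length match spanning the junction is found exactly
once and every reported start position stays in 1..length — which also makes
site multisets rotation-invariant by construction. Flanking windows anchor
both segments at the junction: 200 intronic + 10 exonic nt per side by
default, clipped (with a warning) at short features. The across-junction
sequence takes 11 nt per side by default — enough to cover a seed site that
straddles the junction; it is configurable. DNA (T) is the internal alphabet
throughout; the RNA alphabet is a display option at FASTA export.

## Motif and miRNA screens

Motif scanning expands IUPAC degeneracy per position (standard code — note
Y = C/T) and counts overlapping occurrences, since RNA-protein binding sites
are not mutually exclusive at scan time. Enrichment compares occurrence
*rates per kilobase of scanned start positions* between a foreground and a
background set — the same universe the Fisher 2×2 table uses, so the fold and
the p-value cannot disagree about denominators. "De novo" discovery is
deliberately modest: k-mer over-representation ranked by Fisher p, not
expectation-maximization motif fitting.

Seed sites pair the miRNA seed (mature positions 2–8, the standard
definition; offset and length configurable) antiparallel against each 7-nt
window: Watson–Crick pairs are (A,T), (U,A), (G,C), (C,G) in (seed, target)
orientation; G:U wobbles are (G,T) and (U,G); N is a mismatch. The default
acceptance rule — total >= 6, Watson–Crick >= 5, wobble <= 1 — reads "one
non-canonical match allowed" as *at most* one wobble, admitting the 7WC,
6WC, 6WC+1wob and 5WC+1wob patterns. Sites are counted per start position
without merging overlaps. Only the sense strand is scanned: the miRNA binds
the circRNA transcript itself.

## Flank features and inverted repeats

GWAS SNPs (catalog-style TSV, trait filtering by regex) and RepeatMasker
repeats (rmsk TSV, 0-based starts converted on load) are assigned to flank
intervals by >= 1-base overlap with inclusive boundaries. "Complementary
repeats" are operationalized as: one repeat in each flanking intron, both
satisfying the family predicate (default: name starts with "Alu"), on
opposite strands — the configuration whose intramolecular base pairing is the
classic back-splicing driver. Within-intron inverted pairs are not counted
by default. No sequence alignment between the repeat copies is attempted;
strand opposition within a family is the proxy.

## The synthetic fixture: what it emulates, and what it does not

`build_fixture()` writes a fully consistent miniature study: a ~60 kb
two-chromosome genome, 12 single-transcript genes (4–8 exons of 120–300 nt,
introns 250–600 nt), 20 true circRNAs reported by all six tool dialects,
2 private low-count decoy junctions per tool (counts <= 2, so the default
filter provably removes them), 2 antisense artifacts, NB counts (means
30–150, dispersion 0.2) for 3 control + 3 disease samples with four planted
|log2FC| = 2 effects, one internal and one junction-spanning perfect miRNA
seed site, a hexamer motif written into the 200-nt junction-proximal intron
segments, GWAS SNPs at intron boundaries (plus off-trait and out-of-flank
decoys), inverted/same-strand Alu placements with a generator-side
brute-force ground truth of which circs carry a complementary pair, and
identity/shift/inversion/partial chain files with inverses. Everything is a
pure function of the seed, byte for byte.

The fixture emulates *bookkeeping reality* — dialect quirks, coordinate
conventions, strand handling, circular topology, planted signals — not
biological reality: no read-level noise, no alternative isoforms, no GC or
repeat structure in the background sequence, single-transcript genes, and
per-tool counts that agree exactly. Green tests therefore certify the
machinery (parsing, normalization, merging, scanning, statistics), not
performance on real tissue data.

Problem sizes used by the test suite and acceptance script — chosen as the
smallest sizes at which each property is sharp: all 16,384 windows for the
seed-scorer oracle; a 1-kb circle and 20 rotations for rotation invariance;
1,000 rows for the filter oracle; ~10-kb chains expanded base by base for the
lift oracle; 1,000 junctions × 3 vs 3 with 10 null and 4 power replicate
simulations for DE calibration; 100 circs (both strands) for the sequence
oracle; 150 + 150 sequences of 1 kb with planted densities 8/kb vs 2/kb for
enrichment recovery.

## Other numerical choices

* Degenerate DE inputs: an all-zero group contributes a 0.5-floor to the
  log-scale variance denominator; identical groups give log2FC = 0 and p = 1
  by the `se = 0` convention.
* Random BSJ sampling is uniform over transcripts, then uniform over the
  `ne(ne+1)/2` ordered exon pairs, so single-exon draws occur at their
  combinatorial share; rejection sampling enforces exclusion of observed
  junctions with a hard error after `n * 1000` attempts.
* `nearest_dist` for an unmatched junction is the smallest tolerance that
  would rescue a match in some transcript (the max over the two coordinates
  of their own minimal boundary distances).
* Ties in k-mer ranking break by fold then lexicographically; ties in
  transcript choice as described above — every ordering a user can observe is
  deterministic.
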