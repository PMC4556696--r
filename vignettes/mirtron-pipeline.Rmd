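---
title: "Annotating and characterizing mirtrons from small RNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and characterizing mirtrons from small RNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrons)
```

## The biological problem

Most microRNAs are cut out of primary transcripts by Drosha and then
processed by Dicer. Mirtrons bypass Drosha entirely: a spliced, debranched
intron folds back on itself into a pre-miRNA-like hairpin and is handed to
Dicer directly. Because splicing chemistry fixes the intron ends at the GT
donor and AG acceptor, mirtron hairpins fall into four biogenesis
subtypes, defined by which hairpin ends coincide with splice sites:

* **conventional** -- both hairpin ends are made by splicing; the hairpin
  *is* the intron;
* **5'-tailed** -- the hairpin sits flush against the acceptor and an
  unstructured 5' tail is resected exonucleolytically;
* **3'-tailed** -- the mirror image: hairpin at the donor, 3' tail removed;
* **two-tailed** -- the hairpin abuts neither splice site and both tails
  are removed.

This package implements the full discovery and characterization pipeline:
collapsed small RNA reads are placed on a genome, assigned to annotated
introns, the hairpin extent and miRNA/star duplex are inferred from read
stacks, the subtype is classified from splice-site offsets, and a tiered
evidence rule combining duplex read counts with Argonaute
immunoprecipitation (Ago-IP) support produces the final call. Downstream
modules quantify terminal heterogeneity, untemplated 3' tailing, 5'-G
decapitation, sequence/length/energy features, host-gene intron counts,
host-mRNA expression correlation and Ago-IP enrichment.

Everything is exercised on a bundled synthetic-data generator with planted
ground truth, so every stage is testable end to end without any external
download.

## The annotation procedure

### Mapping

Reads are collapsed to species and matched exactly against both genome
strands. A read that fails to match is trimmed one 3' nucleotide per
iteration -- at most 4 iterations, never below 17 nt -- and reported at the
first iteration with a hit (`map_iterative()`). The trimmed 3'
nucleotides are retained: they are, by construction, the genome-mismatching
read suffix, the raw material of untemplated-tail calling. Only exact
matching is supported; the mismatch knob exists in `mapping_config()` for
interface stability and rejects non-zero values. Multi-mapped reads keep
all placements and contribute fractional weight 1/n to each locus; reads
are assigned to an intron only on the host gene's sense strand
(`assign_to_introns()`). A placement whose 3' end runs at most 6 nt past
the splice acceptor (5' end inside the intron) is kept as a locus read
with its genomic overhang recorded -- this is deliberate, because under
splice-anchored tail calling those nucleotides are tail even when they
match the genome, and routing them to a junction-overlap bin would
blind the tail analysis to genomic-confounded tails. All other
boundary-spanning placements are excluded from locus evidence.

### Hairpin extent, subtype and duplex geometry

Within an intron, the weight-dominant read species defines one arm and the
heaviest species overlapping it by less than half a read length defines
the other (ties break to the lower coordinate). Hairpin ends snap to the
donor/acceptor when within 1 nt (`splice_tolerance`), reflecting the
+/- 1 dominant heterogeneity observed at splice-defined termini. Reads are
bucketed as 5p, 3p (terminus within 3 nt of the respective hairpin end),
loop (fully between the arms) or other.

Subtype classification compares the hairpin-end offsets from the splice
sites with two bounds: within 1 nt counts as abutting, and at least
`two_tailed_min_offset = 5` nt from both sites defines two-tailed. The
band in between is genuinely ambiguous -- the literature gives no numeric
boundary for "did not directly abut" -- so offsets there snap to the
nearest class and the call carries an `ambiguous` flag rather than being
silently forced.

The hairpin is folded and the duplex geometry read off the pair table.
Overhangs are computed from the duplex *register* -- the median of
`i + partner(i)` over all arm-arm pairs -- rather than from the terminal
base pair, which makes the computation robust to locally unpaired or
shifted ends. Dicing geometry passes when both 3' overhangs lie in
[-1, 4] nt and at least 12 base pairs link the arms. The window brackets
the canonical 2-nt 3' overhang, admits the occasional 4-nt case seen at
real loci, and rejects the unstructured stacks that degradation produces.

### The folding engine

`fold_hairpin()` uses a deterministic dynamic program over nested
structures with a proxy energy model: G:C = -3, A:U = -2, G:U = -1, +4
per hairpin loop, +2 per interior loop or bulge, +4 per multiloop,
stacked pairs and external bases free, minimum loop 3 nt. This is not a
thermodynamic model; its contract is (a) determinism across runs and
platforms, (b) ranking stable stems below shuffled sequence, and (c)
register-stable recovery of planted stems. The interior-loop penalty is
load-bearing for (c): pure base-pair maximization will bulge around any
stem imperfection and slide the register, corrupting overhang calls. The
perfect 10-bp G:C stem `GGGGGGGGGGAAAACCCCCCCCCC` scores
10(-3) + 4 = -26, and the implementation is verified against exhaustive
structure enumeration on short sequences. An RNAfold backend
(`backend = "rnafold"`) is available when ViennaRNA is on the PATH;
energy scores are comparable within a backend only.

### Tiered evidence criteria

Tiers are evaluated in order; the first match wins
(`apply_criteria()`):

1. `confident_duplex`: >= 50 duplex (mature + star) reads with >= 5 star
   reads, and dicing geometry passes;
2. `confident_agoip`: >= 100 mature-arm reads of which >= 20 from Ago-IP
   libraries, and dicing passes -- strand selection can be asymmetric
   enough to suppress star accumulation, and Ago loading is direct
   evidence of a functional duplex;
3. `rescue_a`: <= 3 star reads but >= 20 Ago-IP reads;
4. `rescue_b`: 3-4 star reads, >= 10 Ago-IP reads, >= 100 total reads;
5. `candidate`: >= 10 total reads;
6. `rejected` otherwise.

Weighted (fractional) counts are rounded half-up before comparison. Loop
and junction-overlap reads never count toward duplex evidence.

## The synthetic-data generator

`sim_config()` fixes the study conditions. Hairpins are built by sampling
a 22-nt 5p arm (G-biased: P(G) = 0.35, P(C) = 0.15, the complementary 3p
arm is correspondingly C-rich, mirroring the composition bias of real
5'-tailed mirtron duplexes), reverse-complementing it into the 3p arm
with 2-nt 3' overhangs at both duplex ends, and joining the arms with a
terminal loop. Two generator choices deserve explanation:

* **Stem imperfections are G:U wobbles, not non-pairing mismatches.** At
  the default 10% rate, positions whose partner is G or T are downgraded
  to the wobble pair. Every planted position still pairs, so the planted
  register is the unique folding optimum and duplex-geometry recovery is
  exact; real mirtron stems carry wobbles in just this way.
* **Terminal loops are drawn from A/C only.** A and C cannot pair with
  each other under any rule the scorer knows, so the loop cannot form
  competing structure or invade the stem. Loops are at least 18 nt so
  the phased loop read survives the 17-nt mapping floor.

Conventional loci get longer loops (mean 38 nt) than tailed loci
(mean 20 nt), reproducing the situation where conventional pre-miRNAs
run noticeably longer (~85 nt) than the ~60-65 nt of tailed and
canonical hairpins. 5' tails are log-uniform on 10-3000 nt; bulk introns
follow a mixture with mode in the 100-200 nt bin and a heavy tail.
Mirtron host genes draw intron counts with mean ~2.7x the bulk mean,
matching the observed excess of introns in mirtron hosts.

Reads: duplex depth per locus per library (default 550, multiplied by a
log-normal per-locus abundance scalar with sdlog 0.5 so loci span a
realistic expression range) splits mature:star binomially at 10:1 odds; 5' ends jitter with distribution
{0: .8, +1: .1, -1: .1}, clipped at 0 for splice-defined 5' ends (the
lariat leaves nothing upstream of the donor to sequence); 3p reads
ending at the acceptor gain untemplated U tails with probability 0.45
and A tails with probability 0.10 (lengths 1/2/3 at .6/.3/.1);
splice-defined 5p reads starting exactly at the donor lose their G with
probability 0.10 (decapitation is applied after jitter, so the expected
"xU" fraction is `j0 * decap + j1`). Loop reads are emitted into
total-RNA libraries only -- loop species are rejected from Ago
complexes -- and control-IP libraries receive only background
degradation reads (1 read per kb of bulk intron). The two exonic
nucleotides downstream of every acceptor are pinned to "CC" so tails
never match the genome; `tail_confound = TRUE` pins them to "TT"
instead, which is the stress test proving that splice-anchored tail
calling is insensitive to genomic confounding while naive calling is
blind to it.

What the generator does *not* emulate: sequencing error, quality scores,
PCR duplicates, isoform structure, alternative splicing, RNA editing,
cross-mapping between paralogous loci, and realistic chromosome-scale
context. Passing tests therefore demonstrate the correctness of the
pipeline's logic under its stated read model, not robustness to every
artifact of real libraries.

## Terminal analyses

Offset profiles (`end_offset_profile()`) are read-weighted (the
alternative, species-weighting, would let a singleton isomiR outvote a
thousand-read species) and use the splice site as reference exactly when
that terminus is splice-defined for the subtype, else the weight-modal
end. Offsets are reported on [-5, +5] with outside mass pooled into the
boundary bins.

Untemplated tails (`call_untemplated_tail()`): with anchoring, every read
nucleotide 3' of the acceptor is tail regardless of genome match;
without, only mapping-trimmed suffixes are. Categories: monoU/diU/multiU,
monoA/diA, U+A mixtures as `mixed`, anything else `other`; per-group
summaries pool categories under 1% of reads into `others`.

xU scoring (`xu_frequency()`) applies only to subtypes whose 5p arm is
splice-defined: reads at the donor with the G present are GU, reads one
nucleotide in are xU, everything else (>= 2 nt in, or upstream starts) is
other; loci with fewer than 10 5p reads are reported undefined rather
than estimated.

## Locus features and expression statistics

Intron length histograms use 100-nt bins with a pooled top bin (15 kb
human-style default). Logos are equal-locus-weighted position frequency
matrices with per-column coverage denominators; the bulk-intron control
anchors at position -65 from the intron end, the average distance of
5'-tailed hairpin starts from their acceptors. Energy comparisons sample
controls without replacement to match the case length distribution in
100-nt bins (a short bin takes the whole bin and clears the `matched`
flag) and test the per-base mean difference by two-sample t-test.
Host-gene intron counts use a trimmed mean dropping the top 2% of genes
and Wilcoxon rank-sum tests against bulk genes. Pre-miRNA length classes
are compared with Mann-Whitney tests -- the underlying report prints only
p-values without naming the test, and the rank-based choice is robust to
the long right tail of conventional-mirtron lengths. Seeds are nt 2-8
(7-mer, conservation) and nt 2-7 (6-mer, mimicry) of the dominant mature
species. The conservation analysis takes the intron homology map as an
input table; the generator simulates a single species, so tests build
homology fixtures directly.

For expression: RPMM/RPKM/RPM follow their standard definitions;
mirtron-host Pearson correlations drop zero-variance pairs with a count
rather than imputing r = 0. The shuffled-label envelope permutes the host
matrix's tissue columns only (one permutation per shuffle), preserving
the mirtron marginal. The envelope itself is *simultaneous*: each
shuffled CDF's sup-deviation from the mean shuffled curve is computed and
the alpha = 0.99 quantile of those deviations sets the band half-width.
By exchangeability a null curve exits this band with probability about
1 - alpha; a pointwise min/max band over the same 100 shuffles would be
exited by a third of null curves somewhere along the curve, which is not
what a 99% envelope should mean. The median of observed correlations is
tested against zero with a two-tailed one-sample Wilcoxon test. Ago-IP
enrichment combines replicate libraries by mean RPM, excludes loci with
zero reads in every group (reporting the count), transforms to
log2(RPM + 0.1) so zero-read loci stay on the log scale, and reports all
pairwise t-tests with Holm adjustment. Discordant expression is simulated as
uncoupling: the mirtron accumulates in only 1-2 tissues, at levels drawn
independently of the host, while the host stays broad -- masking alone
would leave the correlation high whenever the kept tissue happens to be
the host's peak.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout; strand flips happen only in
the I/O layer, and everything downstream works in sense-of-host-gene
orientation. Ties in dominant-species selection break to the lower
coordinate; equal-weight arm choice calls the 5p arm mature. Reads with
U are normalized to T at ingest; non-canonical splice dinucleotides warn
but do not drop. Loci with fewer than two distinct read species are
skipped (no duplex is possible); a stage failure at one locus marks it
`errored` and never aborts the run. Result tables are written
tab-separated with a deterministic primary-key sort and 7 significant
digits, so reruns are byte-identical and round-trips are lossless to
1e-6 relative.

The default analysis scale -- ~60 genes, ~700 introns, 8 libraries of
~18k reads, 7 tissues -- was chosen so a full simulate-to-report run
completes in about a minute while every evidence threshold is exercised
at 10x its boundary. The numbered scripts under `analysis/` run these
stages against on-disk intermediates; each stage consumes only files the
previous stage wrote, so deleting downstream outputs and rerunning
reproduces them exactly.

## Known limitations

* The folding proxy has no thermodynamic meaning; absolute energies are
  not comparable to RNAfold output, only rankings within a backend.
* Hairpin-extent inference assumes the two dominant species are the
  mature/star arms; loci dominated by degradation ladders can produce
  `other`-heavy buckets and fail the duplex check (by design, but with no
  attempt at rescue).
* Multi-mapper weighting (1/n placements) is a convention; the original
  meta-analyses resolved such reads by manual locus vetting, which an
  automatic pipeline cannot reproduce and replaces with the `ambiguous`
  and tier machinery.
* The expression simulator links mirtron abundance to host junction
  reads multiplicatively; it does not model transcriptional bursting,
  isoform switching or measurement depth differences between platforms.
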