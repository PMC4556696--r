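# mirtrons

Discovery and characterization of **mirtrons** — the introns whose
spliced, debranched lariats fold into pre-miRNA hairpins and enter the
miRNA pathway through Dicer, bypassing Drosha — from collapsed small RNA
sequencing reads and an intron annotation.

The package is written for small-RNA / regulatory-genomics analysts. It
implements the complete pipeline:

* **Mapping** — exact-match placement of collapsed reads on both genome
  strands with iterative 3' trimming (1 nt per iteration, ≤ 4 iterations,
  ≥ 17-nt floor); the trimmed, genome-mismatching suffix is retained as
  the substrate of untemplated-tail calling.
* **Annotation** — per-intron read stacks define the hairpin extent
  (dominant read ends, snapped to splice sites within 1 nt); a
  deterministic folding engine infers the miRNA/miRNA\* duplex and its 3'
  overhangs; loci are classified as conventional, 5'-tailed, 3'-tailed or
  two-tailed mirtrons and assigned an evidence tier:
  `confident_duplex` (≥ 50 duplex reads, ≥ 5 star reads, dicing geometry
  in the [−1, 4] nt overhang window), `confident_agoip` (≥ 100 mature
  reads, ≥ 20 from Ago-IP), two narrow Ago-IP rescue tiers, `candidate`,
  or `rejected`.
* **Terminal analyses** — 5'/3' isomiR offset profiles; untemplated 3'
  uridylation/adenylation called against the splice-acceptor anchor
  (counted as tail *regardless of genome match*); 5'-G decapitation
  ("xU") fractions at splice-defined 5p arms.
* **Locus features** — intron-length histograms, anchored nucleotide
  logos, folding energy per base against length-matched intronic
  controls, host-gene intron-count statistics with 2%-trimmed means,
  pre-miRNA length statistics, seed conservation and seed mimicry.
* **Expression statistics** — RPMM/RPKM/RPM normalization, mirtron–host
  Pearson correlation across tissues with a 100-shuffle α = 0.99
  confidence envelope and one-sample Wilcoxon median test, expression
  breadth, and Ago-IP enrichment CDFs on log2(RPM + 0.1) with
  Holm-adjusted pairwise t-tests.
* **Synthetic data** — a generator that plants ground-truth loci of every
  subtype (splice-defined duplex reads with 2-nt 3' overhangs, strand
  asymmetry, loop reads absent from Ago-IP, 3' U/A tailing, 5'-G
  decapitation, 5' jitter, intronic background, planted expression
  regimes), so the whole pipeline is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the full study on simulated
data with planted truth:

```sh
Rscript analysis/01_simulate.R 1       # seed 1
Rscript analysis/02_annotate.R
Rscript analysis/03_terminal_heterogeneity.R
Rscript analysis/04_locus_features.R
Rscript analysis/05_expression.R
```

Stage 2 prints the tier table and recovery against the planted truth:

```
Tier x subtype table:
                candidate confident_duplex rejected
  conventional          0                6        0
  fivep_tailed          0               10        1
  threep_tailed         1                4        4
  two_tailed           47                2      247
Recovery of 22 planted mirtrons: recall 1.000, precision 1.000
Subtype accuracy on true positives: 1.000
```

All 22 planted mirtrons are recovered at `confident_duplex` with correct
subtypes; the `candidate`/`rejected` rows are bulk introns that attracted
background degradation reads but never pass the duplex criteria. Stage 3
then reports the terminal phenotypes (the simulation tails 3p reads at
the splice acceptor with probability 0.45 U / 0.10 A and decapitates
splice-defined 5p reads at rate 0.1 on top of 10% +1 jitter):

```
 fivep_tailed     none 0.455641255
 fivep_tailed    monoU 0.271573888
 fivep_tailed      diU 0.137025859
 ...
xU summary over 10 loci with >= 10 5p reads: mean xU 0.198; 10/10 loci >= 10% xU
```

and stages 4–5 the comparative features:

```
Energy/base: mirtron hairpins -0.664 vs matched controls -0.493 (t-test p = 1.58e-08, matched = TRUE)
Host-gene intron counts: mirtron hosts 18.4 (trimmed) vs bulk 7.1, rank-sum p = 1.20e-10
Mirtron/host junction correlation over 22 loci: median r = 0.982, Wilcoxon median p = 2.38e-06
Ago-IP enrichment: ago_ip vs control_ip Holm-adjusted p = 1.75e-29
```

The same machinery runs on real inputs: a genome FASTA, a BED6 intron
annotation whose name field encodes `host_gene|intron_index|intron_count`,
collapsed FASTA (`id_xN`) or FASTQ read libraries, and a TSV manifest of
library classes (`total`, `ago_ip`, `control_ip`, `input`).

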