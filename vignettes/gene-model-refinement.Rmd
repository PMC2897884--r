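---
title: "Validating and correcting gene models with RNA-seq evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and correcting gene models with RNA-seq evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnarefine)
library(dplyr)
```

## The problem

Automated structural annotation of compact, intron-dense genomes — fungal
genomes are the archetype, with five or more short introns per gene and
exons down to a few codons — routinely misplaces splice sites, invents
introns, merges over real exons, and truncates UTRs. Deep short-read RNA
sequencing observes the spliced product directly, at a redundancy that EST
libraries never reached. `rnarefine` turns that evidence into a per-gene
verdict and, where possible, a repaired structure. Each predicted model
ends as **validated** (the expressed structure matches the prediction),
**corrected** (the reads changed it), or **failed** (the evidence could not
be assembled into a clean structure).

The pipeline is deliberately targeted rather than a de novo assembler: it
starts from the existing annotation, spends effort only where the reads
disagree with it, and places no prior on splice-site dinucleotides or
intron lengths — which is what lets it recover exons far shorter than
motif-based predictors accept, at the acknowledged cost of occasional
ambiguity in the exact genomic placement of a junction.

## The five stages

**1. Alignment and evidence sets.** Fixed-length reads (46 nt by default)
are aligned ungapped, in both orientations, against the genome scaffolds
and against the spliced transcripts of the predicted models, reporting
every placement within a Hamming-distance budget (`max_mismatch = 2`).
Three evidence sets follow: Set 1, reads on the genome; Set 3, reads on
the model transcripts; Set 2, the Set-3 alignments of reads with *no*
genome alignment — reads whose only explanation is a splice junction.
The aligner is a deterministic, quality-blind stand-in for a production
short-read aligner; everything downstream consumes only counts, and a SAM
import path (`read_alignments_sam()`) lets a production aligner be
substituted at scale.

**2. Expression filter.** Expression is summarized as reads per kilobase
of transcript (RPK); with fixed-length reads, mean depth is
`RPK × read_len / 1000`, so 500 RPK at 46 nt is a mean depth of 23 and
60 RPK a depth of about 3. The default working threshold is
`min_rpk = 500`: deviation flagging is a hard per-base test, and below
roughly twenty-fold coverage, dips of sampling origin become hard to
separate from annotation errors. The filter is a config knob — 60 RPK
reproduces the low-coverage regime.

**3. Deviation flagging (the FDM).** For each expressed gene the model's
transcript is walked base by base: a position whose combined per-base
evidence (`genome_align + border_align`) falls below `threshold = 2`
alignments is replaced by the flag character `X`; additionally each
predicted intron whose junction is crossed by fewer than `threshold`
spanning reads receives a junction flag. Without the junction rule a
spurious intron flanked by well-covered exons would never be flagged.
Post-processing then concatenates adjacent flags, absorbs expressed
islands shorter than `min_segment = 36` bp (too short to host an 18-mer
probe on each side) into the surrounding flag, and converts terminal
flags into `E` marks that are noted and removed — termini are repaired by
extension, not bridging.

Two evidentiary details matter here. Junction support requires at least
`min_overhang = 3` bases on each side of the junction, so alignments that
merely graze a boundary do not count. And junction support counts only
**mismatch-free** alignments (`junction_max_mismatch = 0`): under a
whole-read budget of two mismatches, a read overhanging a *wrong* junction
by three to five bases still aligns whenever one or two of the overhang
bases match by chance, and with a threshold of only two reads such
accidents would routinely let a merged-intron error masquerade as a
confirmed junction. Exactness is asked only of the junction-crossing
evidence, not of the read as a whole.

**4. Bridging and extension (the BES).** Each internal flag is spanned by
probe-seeded consensus assembly over the read set. An exact 18-mer probe
is taken 6 bp upstream and downstream of the flag; the assembler grows a
contig from the start probe by repeatedly tallying, over every exact
occurrence of the contig's terminal 18-mer in the reads (both
orientations), the bases that follow, and emitting per position the base
carried by a strict majority (> 50 %) of the tally — ties, sub-majority
pluralities, and zero coverage give `N`. Growth succeeds when the end
probe appears as an exact substring, and gives up after `max_look = 27`
iterations or more than `max_n = 6` cumulative `N` calls. If the 6-bp
probes fail (a read error or a boundary misalignment can corrupt a probe
site), probes at 15 and then 21 bp are tried; only then is the flag
unresolved. Termini are extended the same way with no end probe and a
strict `N` budget of 1, seeded with the FDM's first and last 18-mers (the
upstream side grows on the reverse complement). The strict-majority rule
is what makes the method behave predictably in the presence of minor
splice variants: the majority form is assembled, a 50/50 mixture yields
`N` and eventually a failure rather than a chimera.

The result, the bridged-and-extended sequence (BES), replaces each flag
*and* the skipped probe margins with assembled sequence, so a bridge also
repairs small errors adjacent to the flag.

**5. Realignment and classification.** The BES is aligned back to a
scaffold window — the model span widened by three times each extension
length — with a splice-aware Smith–Waterman variant: match +8, mismatch
−12, `N` against anything +4, gaps in the scaffold −24 per base, gaps in
the BES (introns) −1 per base, window overhang free, and **no aligned
block shorter than 4 BES bases**, enforced inside the dynamic program by
a capped run-length state so the optimum is global under the constraint.
Before alignment, 5 % of each terminus extension is trimmed (the
outermost consensus bases are the least supported; the trim is applied
per extension). If the alignment is not acceptable — fewer than 90 % of
non-`N` BES bases aligned, or identity below 95 % over informative
columns — the reverse complement is tried; minus-strand genes are
recovered on the second attempt. Aligned blocks separated only by
BES-side insertions merge into exons; window gaps become introns. A model
is *corrected* when at least one flag was bridged, the exon count
changed, or the expressed length changed by more than 10 % in absolute
value; otherwise it is *validated*.

Ties deserve a note: at equal score, transcript-to-genome placement is
frequently ambiguous (any short exon-edge fragment that recurs inside an
intron produces an equal-scoring relocation). The DP therefore optimizes
lexicographically — score first, then **fewest intron openings** — and
breaks remaining ties with a fixed predecessor preference and the
earliest window offset. Fewest-introns is not cosmetic: without it, every
equal-scoring shatter of an exon edge into the neighbouring intron is as
good as the contiguous truth.

## The enrichment statistic

Functional enrichment of a selected gene set against a background uses
the cumulative binomial distribution `B(x; n, p)` (computed via
`pbinom`), with `x` the selected-set count carrying an annotation, `n`
the selected-set size, and `p` the background fraction. The reported
p-value is `1 − B(x; n, p) = P(X > x)` — the tail *excluding* the
observed count, one notch more conservative than the conventional
`P(X ≥ x)`, which is available via `inclusive = TRUE`. Annotations pass
at `p < 0.001` with at least 10 selected models carrying the annotation.
No multiple-testing correction is applied at this stage.

## Synthetic ground truth

Because every stage is sensitive to base-level detail, the package ships
a generator (`generate_truth_set()`, `simulate_reads()`,
`exon_series_fixture()`) that builds genomes with fully known gene
structures, derives corrupted "predicted" models from them, and simulates
reads **from the true structures** while the pipeline sees only the
corrupted models. Corruption types: a splice-site shift (default 4 bp
into the intron), a spurious intron carved into a long exon (80 bp), an
omitted internal exon, and clipped or over-extended termini (15 bp).
Defaults describe a compact fungal-style complement: 3–8 exons per gene,
exons 60–300 bp with one guaranteed long internal exon, introns
50–200 bp, one corruption per gene spread evenly over the five types.

Three generator choices make "exact recovery of the true exon blocks" a
well-posed target rather than a coin flip:

* **Unambiguous junctions.** A junction can slide one base whenever the
  last intron base equals the last exon base (or symmetrically at the
  acceptor); every sequence-based aligner then faces an exact tie. The
  generator forces those boundary bases to differ.
* **Distinguishable internal exons.** If an internal exon's first three
  bases equal the next exon's first three (or last-vs-last with the
  previous), then after *omitting* that exon the merged junction is
  supported by genuinely mismatch-free reads and the omission is
  undetectable in principle. The generator edits the third boundary base;
  the same guard is applied to the segment carved out by a spurious
  intron.
* **Terminal corruptions are modest (15 bp).** The method trims 5 % of
  each extension before realignment, so a terminus restored through an
  extension of length `L` is reported `floor(0.05 L)` bases short *by
  design*. Boundary errors under ~20 bp — the common gene-caller case —
  are below the trim floor and recoverable exactly; whole-exon
  truncations are supported by the generator but are not part of the
  default exact-recovery benchmark.

Read simulation: `step1` tiling emits every 46-nt window of every true
transcript once per pass (alternating orientation), giving deterministic,
uniform interior coverage of 46 per pass — at the default depth target of
23 a single pass more than suffices, and the read count lands near
955 RPK, comfortably above the 500 RPK filter. `random` mode draws
`depth × len / 46` uniform starts (500 reads per kilobase at depth 23,
mirroring the RPK↔depth correspondence). Substitution errors are
available (`read_error_rate`); the default benchmarks are error-free.

What the generator does **not** emulate: coverage biases (GC, 3′ bias),
quality scores, indels, multi-copy gene families, alternative splicing,
and scaffold `N` runs. Passing the recovery benchmarks therefore
demonstrates the correctness of the machinery under clean evidence, not
robustness to every artifact of real libraries.

## What the benchmarks show

```{r benchmark, eval = FALSE}
truth <- generate_truth_set(fixture_config(seed = 1))
reads <- simulate_reads(truth)
run <- run_pipeline(pipeline_config(truth$genome,
                                    truth$corrupted_models, reads))
glance(run)
```

On the default 20-gene corrupted fixture (depth 23, error-free step-1
reads) the pipeline restores the exact true exon blocks of every gene;
the regression threshold asserted in the test suite is ≥ 95 %. On the
uncorrupted fixture every gene is validated. The short-exon series
(three-exon genes, 200-bp flanks, 80-bp introns, middle exon 3–30 bp
omitted from the prediction) is recovered exactly down to middle exons of
5–7 bp depending on seed: 3 bp sits below the 4-bp minimum block of the
realigner, and at 4–6 bp a chance second occurrence of the short exon's
sequence inside the merged intron occasionally produces an equal-scoring
relocation that the tie-break resolves away from the truth. These
problem sizes (tens of genes, scaffolds of a few kilobases, a few tens
of thousands of reads) were chosen so the full suite runs comfortably on
a laptop while still exercising every code path at realistic per-gene
scale.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 input/output is
  1-based inclusive, shifted exactly once at the file boundary.
* FASTQ qualities are read and discarded; the method is quality-blind.
* Probes containing `N` cannot match (the probe index stores only exact
  ACGT windows); flag resolution then advances to the next probe offset.
* The bridging loop checks for the end probe *before* testing the `N`
  budget, so a bridge that succeeds on the same iteration that first
  accrues `N`s is still a success; the contig is truncated at the end of
  the first end-probe occurrence.
* In extension mode the trailing `N` run is stripped, so a terminus
  extension never ends in unknown bases.
* An FDM whose every base is flagged produces an empty working sequence;
  the gene fails downstream with `no_sequence` rather than erroring.
* A BES retaining any unresolved `X` is classified failed without an
  alignment attempt.
* Alignment acceptance (90 % aligned, 95 % identity) and the reverse
  complement retry are the package's own operationalization of "failed
  alignment"; both thresholds are configurable in `pipeline_config()`.

## Known limitations

* One transcript per locus: when two splice forms are simultaneously
  present, the strict-majority consensus assembles the majority form if
  it exceeds 50 % at the divergent sites, and otherwise degrades to `N`
  and failure. Splice-variant discovery is out of scope.
* Junction placement inherits the ambiguity of pure sequence evidence;
  the tie-break makes it deterministic, not biologically informed. Splice
  dinucleotides are deliberately not used for placement.
* Terminus recovery is bounded by the 5 % extension trim, and extension
  range is bounded by `max_look × 18` bases per terminus.
* The ungapped stand-in aligner is quadratic and suited to desk-scale
  genomes; for real genomes, import alignments from a production aligner
  through the SAM front end.
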