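# rnarefine

Validate and correct predicted gene models with deep RNA-seq read
evidence.

Automated structural annotation of intron-dense genomes (fungi are the
archetype: ~5 introns per gene, exons down to a few codons) routinely
misplaces splice sites, invents introns, merges over short exons, and
truncates termini. `rnarefine` compares each predicted model against
aligned short reads, flags every base and every predicted splice junction
that the expression data do not support, repairs the flagged regions by
probe-seeded consensus assembly of the reads, realigns the repaired
transcript to the genome to recover the corrected exon/intron structure,
and classifies the model as **validated**, **corrected**, or **failed**.

## The method in brief

For each expressed gene (reads per kilobase `RPK ≥ 500` by default; mean
depth = `RPK × read_len / 1000`, so 500 RPK ≈ depth 23 at 46-nt reads):

1. **Evidence sets.** Reads are aligned ungapped (Hamming distance ≤ 2,
   both orientations, multi-mappers kept) to the genome (Set 1) and to
   the spliced model transcripts (Set 3); Set 2 = Set 3 restricted to
   reads with no genome alignment — the junction-spanning evidence.
2. **Flagged deviations (FDM).** Walking the model transcript, every
   position with combined coverage `< 2` becomes an `X` flag, and every
   predicted intron with `< 2` mismatch-free spanning reads (≥ 3 bp
   overhang on each side) gets a junction flag. Adjacent flags merge;
   expressed islands `< 36` bp between flags are absorbed; terminal
   flags are noted as `E` and removed.
3. **Bridge and extend (BES).** Each internal flag is spanned by
   consensus assembly anchored on exact 18-mer probes taken 6 (then 15,
   then 21) bp from the flag; the contig grows 18 bases at a time by
   strict-majority vote (> 50 %; ties give `N`) over every exact probe
   occurrence in the reads, until the end probe appears (success) or the
   budgets run out (`max_look = 27` iterations, `max_n = 6` unknowns).
   Termini are extended the same way with no end probe and `max_n = 1`.
4. **Splice-aware realignment.** The BES is aligned to its scaffold
   window (model span + 3 × each extension; 5 % of each extension
   trimmed) under match +8, mismatch −12, `N` +4, gap-in-scaffold −24,
   gap-in-BES (intron) −1, free window overhang, and a hard minimum
   aligned-block length of 4 BES bases enforced inside the dynamic
   program. Failure to align (< 90 % of bases aligned or < 95 %
   identity) triggers a reverse-complement retry.
5. **Classification.** Corrected iff ≥ 1 flag was bridged, the exon
   count changed, or |size change| > 10 %; validated otherwise; failed
   if flags could not be bridged or nothing aligned.

A cumulative-binomial annotation-enrichment statistic is included:
`p = 1 − B(x; n, p₀)` with `B` the binomial CDF, filtered at `p < 0.001`
and ≥ 10 annotated models (`annotation_enrichment()`).

A generator of fully known synthetic truth sets (genome, true models,
corrupted "predicted" models, simulated reads) makes every stage testable
end to end with no external data: reads are simulated from the *true*
structures while the pipeline sees only the *corrupted* models.

## Worked example

Simulate six genes (one structural corruption each — a shifted splice
site, a spurious intron, an omitted exon, clipped/extended termini, and
one left intact), run the pipeline on the corrupted models, and compare
with the truth:

```r
library(rnarefine)
library(dplyr)

truth <- generate_truth_set(fixture_config(seed = 1, n_genes = 6,
                                           n_scaffolds = 2))
reads <- simulate_reads(truth)   # 6,930 tiled 46-nt reads
run <- run_pipeline(pipeline_config(truth$genome,
                                    truth$corrupted_models, reads))
tidy(run)
#> # A tibble: 6 × 8
#>   gene_id   rpk expressed flags_found flags_bridged outcome   exon_delta
#>   <chr>   <dbl> <lgl>           <int>         <int> <chr>          <int>
#> 1 gene001  832. TRUE                1             1 corrected          0
#> 2 gene002  962. TRUE                0             0 validated          0
#> 3 gene003  918. TRUE                1             1 corrected         -1
#> 4 gene004  931. TRUE                1             1 corrected          1
#> 5 gene005  965. TRUE                0             0 validated          0
#> 6 gene006  965. TRUE                0             0 validated          0
glance(run)
#> # A tibble: 1 × 4
#>   expressed validated corrected failed
#>       <int>     <int>     <int>  <int>
#> 1         6         3         3      0
```

Reading the report: `gene001` carried a shifted splice site — one flag
was found and bridged, the exon count is unchanged, and the model is
corrected; `gene003` had a spurious intron (one exon fewer after repair
merges the split exon back together); `gene004` had an omitted internal
exon (one exon more after recovery). The terminus corruptions (15 bp)
are repaired by extension without flags and fall under the 10 % size
criterion, so those models count as validated. Comparing
`corrected_models(run)` with `truth$true_models` shows all six genes
restored to exactly the true exon blocks.

`autoplot(run)` summarizes outcomes; `autoplot(coverage_profile(...))`
draws per-gene coverage with the exon track. Results are written as
`corrected.gff3`, `bes.fa`, `fdm.fa` (+ anchor table), and `report.tsv`
when `pipeline_config(outdir = ...)` is set, and `exec/rnarefine`
provides `simulate` / `run` / `enrich` subcommands over the same
functions.

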