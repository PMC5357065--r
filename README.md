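# editome

Detection and analysis of RNA editing in haploid genomes from RNA-seq
pileup counts.

## What this is for

In a haploid organism (the motivating system is a dinoflagellate coral
symbiont, haploid in its vegetative state), a transcribed genomic
position where RNA-seq reads show the reference base mixed with another
base at intermediate frequency cannot be a heterozygous site — after
artefacts are excluded, it is evidence of RNA editing. `editome` is for
researchers who have per-site base counts (REDItools-style tables or
plain-text SAM alignments), a genome FASTA and a GFF3 annotation, and
want to:

1. **Call edited sites.** At coverage *n* with *k* non-reference reads,
   sequencing error is modelled as *K* ~ Binomial(*n*, *p*) with
   *p* = 0.01 (Phred 20, the conservative maximum); the site p-value is
   the upper tail P(*K* ≥ *k*), BH-corrected over all candidate sites,
   called at corrected *p* < 0.01.
2. **Filter artefacts.** Five independent predicates with a stage
   audit: edit frequency within [5%, 95%]; 201-bp sequence-context
   uniqueness (BLAST-table or built-in seed-and-extend mode); ≤ 85%
   strand bias of edit-supporting reads; distance > 9 bp from intron
   ends; DNA-seq concordance.
3. **Characterise spatial structure.** Length-normalised positional
   histograms, a one-sided binomial test for 5′-end enrichment, and a
   Monte-Carlo neighbour-distance clustering test (10,000 within-gene
   shuffles, χ² on pooled distance bins).
4. **Test differential editing.** Per gene and stressor-vs-control
   contrast, a binomial GLM
   `cbind(edited, unedited) ~ condition * position` on
   replicate × position cells, tested by analysis of deviance against
   the position-only model, BH across genes, significant at corrected
   *p* < 0.05.
5. **Annotate effects.** SnpEff-style classes (UTRs, intron,
   synonymous/non-synonymous, start/stop gain/loss) from the gene
   models and standard genetic code, per-class Fisher + BH contingency
   analysis, the 20×20 amino-acid change matrix, and non-synonymous vs
   synonymous delta-shift comparisons.
6. **Prepare motif inputs.** Per-edit-type 201-bp sequence contexts in
   genic or exonic (spliced) frame with a train/test split, for an
   external motif tool.

A first-class synthetic-data module (`generate_reference()`,
`generate_editome()`, `simulate_counts()`, `simulate_sam()`) generates
genomes, true editomes and count tables with the statistical structure
the analysis assumes, so the whole pipeline is testable offline.

## Worked example

```r
library(editome)

# a synthetic study: 20 genes, 4 conditions x 4 replicates
cfg   <- simulation_config(seed = 5, n_genes = 30, mean_edits_per_gene = 4,
                           diff_fraction = 0.3, edited_gene_fraction = 0.6)
ref   <- generate_reference(cfg)
truth <- generate_editome(cfg, ref$genome, ref$gene_models)

# pooled calling run + per-sample tables
truth$f_pooled <- rowMeans(truth[paste0("f_", cfg$conditions)])
pooled <- simulate_counts(cfg, ref$genome, truth, "pooled", 1)
sites  <- call_edits(pooled)
sig    <- sites[sites$significant, ]

fr   <- apply_filters(sig, ref$genome, ref$gene_models)
fr$audit
#>         stage remaining
#>         input        80
#>     frequency        80
#>    uniqueness        80
#>   strand_bias        80
#>   intron_edge        80
#>           dna        80
surv <- orient_edits(fr$survivors, ref$gene_models)

# differential editing across the three stressors
samples <- expand.grid(condition = cfg$conditions, replicate = 1:4)
counts  <- setNames(lapply(seq_len(nrow(samples)), function(i)
  simulate_counts(cfg, ref$genome, truth, samples$condition[i],
                  samples$replicate[i], positions = truth[c("contig", "pos")])),
  paste0(samples$condition, "_rep", samples$replicate))
samples$sample_id <- names(counts)

prof <- build_gene_profiles(surv, counts, samples)
de   <- differential_editing(prof, c("cold", "heat", "dark"))
de
#> Differential editing (q < 0.05):
#>   cold: 4 of 17 tested genes significant
#>   heat: 4 of 17 tested genes significant
#>   dark: 4 of 17 tested genes significant
#>   union: 4 gene(s); 4 responding to multiple stressors
```

The audit shows how many sites remain after each filter stage (here the
planted truth avoids every artefact, so nothing is removed); the
differential summary counts genes whose editing pattern shifts under
each stressor — in this simulation 4 of the 5 planted differential genes
are testable and all 4 are recovered.

Effect annotation and the contingency analysis:

```r
ann <- annotate_effects(surv, ref$gene_models, ref$genome)
table(ann$effect)
#>  3' UTR  5' UTR  Gain of stop codon  Intron  Non-synonymous coding  Synonymous coding
#>       3       6                   3      11                     36                 12
sub <- ann[ann$gene_id %in% de$summary$union_genes, ]
effect_contingency_tests(sub, ann)   # per-class Fisher + BH
```

## Command line

```sh
Rscript -e 'editome::editome_cli()' simulate --seed 3 --genes 20 --out sim/
Rscript -e 'editome::editome_cli()' run --config pipeline.ini
```

`run_pipeline()` consumes an INI-style config (`[inputs]` genome, gff,
samples, pooled, dna, blast_hits; `[params]` thresholds and seed;
`[output]` dir) and writes called sites, survivors, the filter audit,
spatial statistics, differential results and effect annotations, plus
`run_metadata.json`; reruns are byte-identical.

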