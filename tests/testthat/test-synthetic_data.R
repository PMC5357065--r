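test_that("generated references are deterministic and structurally valid", {
  cfg <- simulation_config(seed = 17, n_genes = 8)
  d1 <- withr::local_tempdir()
  r1 <- generate_reference(cfg, fasta_path = file.path(d1, "a.fa"),
                           gff_path = file.path(d1, "a.gff3"))
  r2 <- generate_reference(cfg, fasta_path = file.path(d1, "b.fa"),
                           gff_path = file.path(d1, "b.gff3"))
  expect_identical(readLines(file.path(d1, "a.fa")),
                   readLines(file.path(d1, "b.fa")))        # byte-identical
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d1, "b.gff3")))
  expect_length(r1$gene_models, 8)
  for (g in r1$gene_models) {
    expect_true(g$cds_ok)
    cds_len <- sum(g$cds$end - g$cds$start + 1)
    expect_equal(cds_len %% 3, 0)
    # CDS starts with ATG and ends with a stop codon, in transcript sense
    cds_seq <- paste(mapply(function(a, b) genome_seq(r1$genome, g$contig, a, b),
                            g$cds$start, g$cds$end), collapse = "")
    if (g$strand == "-") cds_seq <- reverse_complement(cds_seq)
    expect_identical(substr(cds_seq, 1, 3), "ATG")
    expect_true(substr(cds_seq, cds_len - 2, cds_len) %in% c("TAA", "TAG", "TGA"))
    # no internal in-frame stops
    codons <- substring(cds_seq, seq(1, cds_len - 3, 3), seq(3, cds_len - 3, 3))
    expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
  }
  # loader round trip agrees with the in-memory models
  m <- load_gene_models(file.path(d1, "a.gff3"))
  expect_setequal(names(m), names(r1$gene_models))
  for (n in names(m)) {
    expect_equal(m[[n]]$exons, r1$gene_models[[n]]$exons)
    expect_equal(m[[n]]$cds, r1$gene_models[[n]]$cds)
    expect_identical(m[[n]]$strand, r1$gene_models[[n]]$strand)
  }
})

test_that("editome truth respects masks, margins and differential design", {
  cfg <- simulation_config(seed = 23, n_genes = 20, diff_fraction = 0.3)
  ref <- generate_reference(cfg)
  truth <- generate_editome(cfg, ref$genome, ref$gene_models)
  expect_gt(nrow(truth), 10)
  mask <- mask_homopolymers(ref$genome, 4)
  expect_false(any(editome:::is_masked(mask, truth$contig, truth$pos)))
  genic <- truth[truth$gene_id != "intergenic", ]
  expect_true(all(intron_edge_filter(genic$contig, genic$pos,
                                     ref$gene_models, filter_config())))
  expect_true(all(genome_base(ref$genome, truth$contig, truth$pos) == truth$ref))
  expect_true(all(truth$ref != truth$alt))
  # differential genes: control and stress frequencies differ
  dg <- truth[truth$differential, ]
  expect_gt(nrow(dg), 0)
  expect_true(all(dg$f_control == cfg$diff_control_freq))
  expect_true(all(dg$f_heat == cfg$diff_stress_freq))
  nd <- truth[!truth$differential, ]
  expect_true(all(nd$f_control == nd$f_heat))
  # pure-error null: zero frequencies everywhere
  cfg0 <- simulation_config(seed = 23, n_genes = 20, edit_freq_range = c(0, 0))
  t0 <- generate_editome(cfg0, ref$genome, ref$gene_models)
  expect_true(all(t0$f_control[!t0$differential] == 0))
})

test_that("simulated counts carry the configured signal and error", {
  cfg <- simulation_config(seed = 29, n_genes = 6, coverage_mean = 200)
  ref <- generate_reference(cfg)
  truth <- generate_editome(cfg, ref$genome, ref$gene_models)
  tab <- simulate_counts(cfg, ref$genome, truth, "control", 1)
  bt <- editome:::base_totals(tab)
  colnames(bt) <- c("A", "C", "G", "T")
  n <- site_coverage(tab)
  ref_n <- bt[cbind(seq_len(nrow(tab)), match(tab$ref, colnames(bt)))]
  # pure-error positions: non-reference fraction ~ error rate
  key <- paste(tab$contig, tab$pos)
  pure <- !(key %in% paste(truth$contig, truth$pos))
  err_frac <- sum(n[pure] - ref_n[pure]) / sum(n[pure])
  expect_equal(err_frac, 0.01, tolerance = 0.15)
  # edited positions: alt fraction ~ truth frequency (f = 0.5 anchor)
  cfg2 <- simulation_config(seed = 29, n_genes = 6, coverage_mean = 200,
                            edit_freq_range = c(0.5, 0.5))
  truth2 <- generate_editome(cfg2, ref$genome, ref$gene_models)
  tab2 <- simulate_counts(cfg2, ref$genome, truth2, "control", 1,
                          positions = truth2[c("contig", "pos")])
  bt2 <- editome:::base_totals(tab2)
  colnames(bt2) <- c("A", "C", "G", "T")
  idx <- match(paste(tab2$contig, tab2$pos), paste(truth2$contig, truth2$pos))
  altn <- bt2[cbind(seq_len(nrow(tab2)), match(truth2$alt[idx], colnames(bt2)))]
  expect_equal(sum(altn) / sum(site_coverage(tab2)), 0.5, tolerance = 0.08)
  # coverage mean close to the negative-binomial mean
  expect_equal(mean(site_coverage(tab)), 200, tolerance = 0.05)
  # determinism
  tab_b <- simulate_counts(cfg, ref$genome, truth, "control", 1)
  expect_identical(as.data.frame(tab), as.data.frame(tab_b))
})

test_that("generated SAM round-trips through the pileup module", {
  cfg <- simulation_config(seed = 37, n_genes = 4)
  ref <- generate_reference(cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim <- simulate_sam(cfg, ref$genome, n_reads = 150, sam_path = sam)
  tab <- pileup_from_sam(sam, ref$genome, end_trim = 9)
  expect_equal(as.data.frame(tab), as.data.frame(sim$expected),
               ignore_attr = TRUE)
})
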