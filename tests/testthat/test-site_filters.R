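test_that("frequency filter bounds are inclusive", {
  cfg <- filter_config()
  expect_equal(frequency_filter(c(0.04, 0.05, 0.5, 0.95, 0.96), cfg),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("strand-bias filter is strict at the threshold", {
  cfg <- filter_config()
  expect_false(strand_bias_filter(9, 1, cfg))        # 0.90 > 0.85
  expect_true(strand_bias_filter(6, 4, cfg))         # 0.60
  expect_true(strand_bias_filter(17, 3, cfg))        # exactly 0.85 passes
  expect_identical(strand_bias_filter(NA, NA, cfg), NA)
  expect_identical(strand_bias_filter(0, 0, cfg), NA)
})

test_that("intron-edge filter removes the first/last 9 bp of introns", {
  fx <- effect_fixture()                             # Gp intron 161-200
  cfg <- filter_config()
  pass <- intron_edge_filter(rep("chrT", 5), c(161, 169, 170, 191, 192),
                             fx$models, cfg)
  expect_equal(pass, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # exonic site passes; 10th base of the intron passes
  expect_true(intron_edge_filter("chrT", 130, fx$models, cfg))
  expect_true(intron_edge_filter("chrT", 170, fx$models, cfg))
})

test_that("DNA concordance distinguishes clean, dirty and uncovered loci", {
  sites <- make_sites("c1", c(5L, 6L, 7L), "C", "T")
  dna <- make_count_table("c1", c(5L, 6L), "C",
                          counts_fwd = list(C = c(30L, 29L), T = c(0L, 1L)))
  strict <- dna_concordance_filter(sites, dna, filter_config(dna_mode = "strict"))
  expect_equal(strict$pass, c(TRUE, FALSE, FALSE))
  flagged <- dna_concordance_filter(sites, dna, filter_config(dna_mode = "flagged"))
  expect_equal(flagged$pass, c(TRUE, FALSE, TRUE))
  expect_equal(flagged$zero_cov, c(FALSE, FALSE, TRUE))
})

test_that("internal uniqueness mode flags duplicated windows only", {
  cfg <- simulation_config(seed = 31, n_genes = 6, duplication = TRUE)
  ref <- generate_reference(cfg)
  dup <- ref$duplicated_region
  expect_false(is.null(dup))
  fcfg <- filter_config()
  idx <- uniqueness_index(ref$genome, fcfg$seed_length)
  centre <- as.integer((dup$src_start + dup$src_end) %/% 2)
  away <- dup$dest_start - 150L          # random intergenic tail, no repeat
  rb <- genome_base(ref$genome, dup$contig, c(centre, away))
  sites <- make_sites(dup$contig, c(centre, away), rb, "T")
  pass <- uniqueness_filter(sites, ref$genome, fcfg, index = idx)
  expect_false(pass[1])                 # window duplicated verbatim elsewhere
  expect_true(pass[2])                  # random locus: self-hit only
})

test_that("BLAST-table uniqueness mode excludes the self hit", {
  g <- random_genome(12, c(cA = 1000))
  sites <- make_sites("cA", c(300L, 600L), genome_base(g, "cA", c(300L, 600L)), "T")
  cfg <- filter_config()
  ids <- uniqueness_window_ids(sites, g, cfg)
  hits <- data.frame(
    qseqid = c(ids[1], ids[1], ids[2]),
    sseqid = c("cA", "cA", "cA"),
    pident = 100, length = 201, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 201,
    sstart = c(200, 700, 500), send = c(400, 900, 700),
    evalue = c(1e-100, 1e-20, 1e-50), bitscore = 300)
  pass <- uniqueness_filter(sites, g, cfg, hits = hits)
  expect_false(pass[1])                 # non-self hit at 700-900
  expect_true(pass[2])                  # only the self window overlaps
  expect_error(
    read_blast_hits(withr::local_tempfile(fileext = ".tsv", lines = character(0))),
    NA)
})

test_that("the cascade removes engineered failures and filters commute", {
  fx <- effect_fixture()
  g <- fx$genome
  # engineered sites: ok, low f, high f, strand-biased, intron edge
  pos <- c(130L, 135L, 138L, 142L, 161L)
  ref <- genome_base(g, "chrT", pos)
  sites <- make_sites("chrT", pos, ref, "T", n = 100L,
                      k = c(50L, 3L, 97L, 50L, 50L))
  sites$edit_fwd <- c(25L, 2L, 49L, 46L, 25L)
  sites$edit_rev <- sites$k - sites$edit_fwd
  dna <- make_count_table("chrT", c(130L, 135L, 138L, 142L, 161L), ref,
                          counts_fwd = list(A = ifelse(ref == "A", 30L, 0L),
                                            C = ifelse(ref == "C", 30L, 0L),
                                            G = ifelse(ref == "G", 30L, 0L),
                                            T = ifelse(ref == "T", 30L, 0L)))
  # uniqueness skipped via a prebuilt empty hits table (toy genome is periodic)
  hits <- read_blast_hits(withr::local_tempfile(lines = character(0)))
  res <- apply_filters(sites, g, fx$models, dna_counts = dna, hits = hits)
  expect_equal(res$audit$remaining,
               c(5L, 3L, 3L, 2L, 1L, 1L))
  expect_equal(res$survivors$pos, 130L)
  expect_true(all(diff(res$audit$remaining) <= 0))   # monotone cascade
  # flags are pure predicates: survivors invariant under cascade order
  flags <- res$sites[paste0("pass_", c("frequency", "uniqueness",
                                       "strand_bias", "intron_edge", "dna"))]
  for (perm in list(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1), c(3, 1, 5, 2, 4))) {
    keep <- rep(TRUE, nrow(flags))
    for (j in perm) keep <- keep & (is.na(flags[[j]]) | flags[[j]])
    expect_equal(res$sites$pos[keep], res$survivors$pos)
  }
  # all-passing and empty inputs
  ok <- apply_filters(sites[1, ], g, fx$models, hits = hits)
  expect_equal(nrow(ok$survivors), 1)
  empty <- apply_filters(sites[0, ], g, fx$models, hits = hits)
  expect_equal(nrow(empty$survivors), 0)
  expect_true(all(empty$audit$remaining == 0))
})
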