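test_that("edit_pvalue matches the direct-summation oracle", {
  # trivial anchors
  expect_equal(edit_pvalue(0, 100, 0.01), 1)
  expect_equal(edit_pvalue(1, 1, 0.01), 0.01)
  # oracle: explicit sum of C(n,i) p^i (1-p)^(n-i) over i >= k
  tail_oracle <- function(k, n, p) {
    i <- k:n
    sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
  }
  expect_equal(edit_pvalue(5, 100, 0.01), tail_oracle(5, 100, 0.01),
               tolerance = 1e-12)
  for (n in c(1, 7, 69, 200)) {
    for (k in unique(c(0, 1, n %/% 2, n))) {
      for (p in c(0.001, 0.01, 0.05)) {
        expect_equal(edit_pvalue(k, n, p), tail_oracle(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(edit_pvalue(5, 4), "k must")
  expect_error(edit_pvalue(0, 0), "n must")
})

test_that("edit_pvalue monotonicity properties", {
  n <- 150
  pv <- edit_pvalue(0:n, n, 0.01)
  expect_true(all(diff(pv) <= 0))                     # non-increasing in k
  pv_n <- vapply(5:300, function(n) edit_pvalue(3, n, 0.01), numeric(1))
  expect_true(all(diff(pv_n) >= 0))                   # non-decreasing in n*p
})

test_that("bh_adjust implements step-up and agrees with stats::p.adjust", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(1:200, 1))^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # widened family inflates q-values
  p <- c(0.001, 0.01)
  expect_true(all(bh_adjust(p, m = 100) >= bh_adjust(p)))
  expect_error(bh_adjust(c(0.5), m = 0), "family size")
})

test_that("call_edits computes frequencies and resolves alleles", {
  # n=69, one alt base with 40 reads (echoes the reported median coverage)
  tab <- make_count_table("c1", c(10L, 20L, 30L), "C",
                          counts_fwd = list(C = c(15L, 9L, 10L),
                                            T = c(20L, 2L, 0L),
                                            G = c(0L, 1L, 0L),
                                            A = c(0L, 0L, 0L)),
                          counts_rev = list(C = c(14L, 7L, 10L),
                                            T = c(20L, 1L, 0L)))
  out <- call_edits(tab)
  expect_s3_class(out, "EditSiteTable")
  s1 <- out[out$pos == 10, ]
  expect_equal(s1$n, 69L)
  expect_equal(s1$k, 40L)
  expect_equal(s1$f, 40 / 69, tolerance = 1e-12)
  expect_true(s1$significant)
  expect_equal(s1$edit_fwd, 20L)
  expect_equal(s1$edit_rev, 20L)
  # multi-edit rule: n=20, alt T=3, alt G=1 -> single edit on T, k=3
  s2 <- out[out$pos == 20, ]
  expect_false(s2$multi_allelic)
  expect_identical(s2$alt, "T")
  expect_equal(s2$k, 3L)
  expect_equal(s2$n, 20L)
  # zero-coverage / reference-only sites are never candidates
  expect_false(30 %in% out$pos)
})

test_that("multi-edit rule needs >=2 reads per allele and >=20% overall", {
  tab <- make_count_table("c1", c(1L, 2L), "A",
                          counts_fwd = list(A = c(15L, 17L),
                                            C = c(3L, 2L), G = c(2L, 1L)))
  out <- call_edits(tab)
  m <- out[out$pos == 1, ]       # n=20, C=3, G=2, overall f=0.25
  expect_true(m$multi_allelic)
  expect_identical(m$alt, "C,G")
  expect_equal(m$k, 5L)
  u <- out[out$pos == 2, ]       # G has 1 read only
  expect_false(u$multi_allelic)
  expect_identical(u$alt, "C")
})

test_that("merge-then-call equals call-on-merged counts", {
  set.seed(5)
  g <- random_genome(5, c(cc = 500))
  tabs <- lapply(1:4, function(i) {
    pos <- 1:500
    ref <- genome_base(g, "cc", pos)
    n <- rpois(500, 20)
    k <- rbinom(500, n, 0.02)
    fw <- list(A = integer(500), C = integer(500), G = integer(500),
               T = integer(500))
    for (b in c("A", "C", "G", "T")) {
      fw[[b]] <- ifelse(ref == b, n - k, 0L)
    }
    alt <- ifelse(ref == "A", "G", "A")
    for (b in c("A", "C", "G", "T")) {
      fw[[b]] <- fw[[b]] + ifelse(alt == b, k, 0L)
    }
    make_count_table("cc", pos, ref, counts_fwd = fw)
  })
  merged <- merge_count_tables(tabs)
  out1 <- call_edits(merged)
  # manual sum
  summed <- as.data.frame(tabs[[1]])
  for (i in 2:4) {
    stopifnot(all(summed$pos == tabs[[i]]$pos))
    summed[editome:::COUNT_COLS] <- summed[editome:::COUNT_COLS] +
      as.data.frame(tabs[[i]])[editome:::COUNT_COLS]
  }
  out2 <- call_edits(site_count_table(summed))
  expect_equal(as.data.frame(out1), as.data.frame(out2))
})

test_that("FDR is controlled under pure error (small-scale)", {
  cfg <- simulation_config(seed = 21, n_genes = 6)
  ref <- generate_reference(cfg)
  tab <- simulate_counts(cfg, ref$genome, truth = NULL)
  out <- call_edits(tab)
  expect_gt(nrow(out), 1000)
  expect_lte(mean(out$significant), 0.01)
})
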