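# build a profile data.frame directly (replicate x position cells)
toy_profile <- function(gene = "g1", conditions = c("stress", "control"),
                        reps = 4, pos = c(100L, 200L), n = 50,
                        f = function(cond, p) 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(condition = conditions, replicate = seq_len(reps),
                      pos = pos, stringsAsFactors = FALSE)
  nn <- rep_len(n, nrow(rows))
  ed <- rbinom(nrow(rows), nn, mapply(f, rows$condition, rows$pos))
  out <- data.frame(gene_id = gene, contig = "c", pos = rows$pos,
                    sample_id = paste0(rows$condition, "_", rows$replicate),
                    condition = rows$condition, replicate = rows$replicate,
                    edited = ed, unedited = nn - ed)
  class(out) <- c("GeneEditProfile", "data.frame")
  out
}

test_that("profiles have one cell per covered replicate x position", {
  fx <- effect_fixture()
  sites <- make_sites("chrT", c(114L, 130L, 50L),
                      genome_base(fx$genome, "chrT", c(114, 130, 50)), "G")
  sites <- orient_edits(sites, fx$models)
  info <- data.frame(sample_id = c("s1", "s2"),
                     condition = c("control", "stress"), replicate = c(1, 1))
  counts <- list(
    s1 = make_count_table("chrT", c(114L, 130L),
                          genome_base(fx$genome, "chrT", c(114, 130)),
                          counts_fwd = list(A = c(10L, 0L), C = c(0L, 12L),
                                            G = c(5L, 3L))),
    s2 = make_count_table("chrT", 114L, genome_base(fx$genome, "chrT", 114),
                          counts_fwd = list(A = 8L, G = 2L)))
  prof <- build_gene_profiles(sites, counts, info)
  # intergenic site (pos 50) contributes nothing; s2 lacks pos 130 (missing)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$edited[prof$sample_id == "s1" & prof$pos == 114], 5L)
  expect_equal(prof$unedited[prof$sample_id == "s2" & prof$pos == 114], 8L)
  expect_false(any(prof$pos == 130 & prof$sample_id == "s2"))
})

test_that("testability filter demands coverage in every replicate", {
  p <- toy_profile(seed = 1)
  expect_equal(unique(filter_testable_genes(p, c("stress", "control"))$gene_id),
               "g1")
  # drop one replicate's coverage at one position -> gene dropped
  p2 <- p[!(p$condition == "stress" & p$replicate == 3 & p$pos == 200), ]
  expect_equal(nrow(filter_testable_genes(p2, c("stress", "control"))), 0)
  # single-position gene dropped
  p3 <- p[p$pos == 100, ]
  expect_equal(nrow(filter_testable_genes(p3, c("stress", "control"))), 0)
})

test_that("identical groups give statistic 0 and p 1", {
  rows <- expand.grid(condition = c("stress", "control"), replicate = 1:4,
                      pos = c(1L, 2L), stringsAsFactors = FALSE)
  prof <- data.frame(gene_id = "g", contig = "c", pos = rows$pos,
                     sample_id = "s", condition = rows$condition,
                     replicate = rows$replicate, edited = 10L, unedited = 30L)
  fit <- fit_differential_glm(prof, c("stress", "control"))
  expect_equal(fit$statistic, 0, tolerance = 1e-8)
  expect_equal(fit$p.value, 1)
  expect_equal(fit$df, 2L)
  expect_equal(unname(fit$shift), c(0, 0))
})

test_that("deviance statistic is invariant under position relabelling", {
  p <- toy_profile(seed = 8, f = function(cond, pos)
    if (cond == "stress") 0.6 else 0.3)
  f1 <- fit_differential_glm(p, c("stress", "control"))
  p2 <- p
  p2$pos <- ifelse(p2$pos == 100L, 900L, 50L)       # relabel levels
  f2 <- fit_differential_glm(p2, c("stress", "control"))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-8)
  expect_gte(f1$statistic, 0)
  expect_gt(f1$p.value, 0)
  expect_lte(f1$p.value, 1)
})

test_that("strong shifts are detected with high power", {
  hits <- vapply(1:20, function(i) {
    p <- toy_profile(seed = 100 + i, f = function(cond, pos)
      if (cond == "stress") 0.8 else 0.2)
    fit_differential_glm(p, c("stress", "control"))$p.value
  }, numeric(1))
  expect_true(all(hits < 0.001))
})

test_that("differential_editing summarises contrasts and overlaps", {
  profs <- list()
  for (g in 1:6) {
    shifted <- g <= 2
    for (cond in c("control", "cold", "heat")) {
      f <- function(c2, pos) if (shifted && c2 != "control") 0.8 else 0.2
      profs[[length(profs) + 1]] <-
        toy_profile(gene = paste0("g", g), conditions = cond,
                    seed = g * 13 + nchar(cond), f = f)
    }
  }
  all_prof <- do.call(rbind, profs)
  res <- differential_editing(all_prof, c("cold", "heat"), "control")
  expect_setequal(res$summary$union_genes, c("g1", "g2"))
  expect_equal(unname(res$summary$per_contrast), c(2L, 2L))
  expect_equal(res$summary$multi_stressor, 2L)
  expect_equal(res$summary$overlap["cold", "heat"], 2L)
  # empty input
  empty <- differential_editing(all_prof[0, ], c("cold"), "control")
  expect_equal(nrow(empty$results$cold), 0)
})

test_that("null simulation keeps the type-I error near nominal (small run)", {
  pv <- vapply(1:150, function(i) {
    p <- toy_profile(seed = 2000 + i)
    fit_differential_glm(p, c("stress", "control"))$p.value
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.12)
  expect_gt(mean(pv < 0.05), 0.005)
})
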