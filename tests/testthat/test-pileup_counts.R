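# SAM text builder: single-end perfect-match reads
sam_text <- function(genome, reads) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$contigs), genome$lengths),
    vapply(seq_len(nrow(reads)), function(i) {
      r <- reads[i, ]
      seq <- r$seq %||% genome_seq(genome, r$contig, r$pos,
                                   r$pos + (r$len %||% 50) - 1)
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*%s",
              r$qname, r$flag %||% 0L, r$contig, r$pos, r$mapq %||% 60L,
              r$cigar %||% paste0(nchar(seq), "M"),
              r$rnext %||% "*", r$pnext %||% 0L, seq,
              if (is.null(r$tags)) "" else paste0("\t", r$tags))
    }, character(1)))
}

test_that("homopolymer mask matches run enumeration", {
  g <- genome_reference(c(c1 = "ACGTACGT", c2 = "AAAAC", c3 = "AAAC",
                          c4 = "CCNNNNGG"))
  m <- mask_homopolymers(g, 4)
  expect_identical(m$positions$c1, integer(0))
  expect_identical(m$positions$c2, 1:4)           # the four A's
  expect_identical(m$positions$c3, integer(0))    # run of 3 below threshold
  expect_identical(m$positions$c4, integer(0))    # N never forms a run
  expect_error(mask_homopolymers(g, 1), "min_run")
  # oracle: brute-force per-position check on a random string
  set.seed(4)
  s <- paste(sample(c("A", "C"), 200, replace = TRUE, prob = c(.7, .3)),
             collapse = "")
  g2 <- genome_reference(c(x = s))
  m2 <- mask_homopolymers(g2, 4)
  ch <- strsplit(s, "")[[1]]
  brute <- which(vapply(seq_along(ch), function(i) {
    run <- i
    a <- i; while (a > 1 && ch[a - 1] == ch[i]) a <- a - 1
    b <- i; while (b < length(ch) && ch[b + 1] == ch[i]) b <- b + 1
    (b - a + 1) >= 4
  }, logical(1)))
  expect_identical(m2$positions$x, brute)
})

test_that("deduplication keys on (contig, start, mate start, strand)", {
  aln <- data.frame(
    qname = paste0("r", 1:6),
    flag = c(99L, 99L, 99L, 147L, 0L, 0L),
    contig = "c1", pos = c(10L, 10L, 10L, 50L, 99L, 99L),
    mapq = 60L, cigar = "50M",
    rnext = c("=", "=", "=", "=", "*", "*"),
    pnext = c(50L, 50L, 60L, 10L, 0L, 0L),
    seq = "A", qual = "*", nh = 1L)
  out <- deduplicate_alignments(aln)
  # r1/r2 same key (one survives); r3 different mate start; r4 different pos;
  # r5/r6 unpaired duplicates keyed without mate
  expect_identical(out$qname, c("r1", "r3", "r4", "r5"))
  distinct <- aln[c(1, 3, 4), ]
  expect_identical(deduplicate_alignments(distinct), distinct)
})

test_that("pileup honours end trim, uniqueness and masking", {
  g <- random_genome(7)
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(qname = c("a", "b", "c"), contig = "contigA",
                      pos = c(101L, 201L, 301L),
                      mapq = c(60L, 0L, 60L), stringsAsFactors = FALSE)
  writeLines(sam_text(g, reads), sam)
  tab <- pileup_from_sam(sam, g, end_trim = 9)
  # 50-bp read, trim 9 -> 32 positions; mapq-0 read contributes nothing
  expect_equal(sum(tab$pos >= 101 & tab$pos <= 150), 32)
  expect_equal(range(tab$pos[tab$pos <= 150]), c(110, 141))
  expect_equal(sum(tab$pos >= 201 & tab$pos <= 250), 0)
  tab0 <- pileup_from_sam(sam, g, end_trim = 0)
  expect_equal(sum(tab0$pos >= 101 & tab0$pos <= 150), 50)
  # non-unique by NH tag
  sam2 <- withr::local_tempfile(fileext = ".sam")
  reads2 <- data.frame(qname = "a", contig = "contigA", pos = 101L,
                       mapq = 60L, tags = "NH:i:3", stringsAsFactors = FALSE)
  writeLines(sam_text(g, reads2), sam2)
  expect_equal(nrow(pileup_from_sam(sam2, g)), 0)
  # masked positions absent
  mask <- structure(list(positions = list(contigA = c(110:141, 310:341),
                                          contigB = integer(0)),
                         min_run = 4), class = "HomopolymerMask")
  expect_equal(nrow(pileup_from_sam(sam, g, mask = mask)), 0)
})

test_that("end-trim equals hard-clipping the same cycles", {
  g <- random_genome(8)
  full <- withr::local_tempfile(fileext = ".sam")
  clipped <- withr::local_tempfile(fileext = ".sam")
  set.seed(2)
  pos <- sample(500:1500, 10)
  reads <- data.frame(qname = paste0("r", seq_along(pos)), contig = "contigA",
                      pos = pos, mapq = 60L, stringsAsFactors = FALSE)
  writeLines(sam_text(g, reads), full)
  creads <- reads
  creads$pos <- creads$pos + 9L
  creads$seq <- vapply(seq_len(nrow(creads)), function(i)
    genome_seq(g, "contigA", creads$pos[i], creads$pos[i] + 31L), character(1))
  creads$cigar <- "9H32M9H"
  writeLines(sam_text(g, creads), clipped)
  t1 <- pileup_from_sam(full, g, end_trim = 9)
  t2 <- pileup_from_sam(clipped, g, end_trim = 0)
  expect_equal(as.data.frame(t1), as.data.frame(t2), ignore_attr = TRUE)
})

test_that("unsupported CIGAR ops skip the record with a counter", {
  g <- random_genome(9)
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(qname = "a", contig = "contigA", pos = 101L, mapq = 60L,
                      cigar = "10M5B35M",
                      seq = genome_seq(g, "contigA", 101, 150),
                      stringsAsFactors = FALSE)
  writeLines(sam_text(g, reads), sam)
  tab <- pileup_from_sam(sam, g)
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "skipped_records"), 1L)
})

test_that("count-table round trip and ref validation", {
  g <- genome_reference(c(c1 = paste(rep("ACGT", 10), collapse = "")))
  tab <- make_count_table("c1", c(2, 10), c("C", "C"),
                          counts_fwd = list(C = c(65L, 30L), T = c(4L, 0L)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, p)
  back <- read_count_table(p, g)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(site_coverage(back), c(69L, 30L))
  # ref disagreement rejected
  tab_bad <- make_count_table("c1", 3, "T", counts_fwd = list(T = 5L))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab_bad, p2)
  expect_error(read_count_table(p2, g), "disagrees")
  # empty file -> empty table
  p3 <- withr::local_tempfile(fileext = ".tsv")
  file.create(p3)
  expect_equal(nrow(read_count_table(p3)), 0)
  # unstranded dialect
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\tA\tC\tG\tT", "c1\t2\tC\t0\t65\t0\t4"), p4)
  u <- read_count_table(p4, g)
  expect_false(attr(u, "stranded"))
  expect_equal(site_coverage(u), 69L)
})

test_that("merging count tables sums counts position-wise", {
  t1 <- make_count_table("c1", c(1, 5), c("A", "G"),
                         counts_fwd = list(A = c(10L, 0L), G = c(0L, 7L)))
  t2 <- make_count_table("c1", c(5, 9), c("G", "T"),
                         counts_fwd = list(G = c(3L, 0L), T = c(1L, 4L)))
  m <- merge_count_tables(list(t1, t2))
  expect_equal(m$pos, c(1L, 5L, 9L))
  expect_equal(m$G_fwd[m$pos == 5], 10L)
  expect_equal(m$T_fwd[m$pos == 5], 1L)
  expect_equal(site_coverage(m), c(10L, 11L, 4L))
})
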