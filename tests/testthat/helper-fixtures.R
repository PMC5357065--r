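# In-code fixtures shared across test files.

# deterministic filler with no homopolymer runs
filler <- function(n, unit = "ACGT") {
  paste(rep(strsplit(unit, "")[[1]], length.out = n), collapse = "")
}

# Toy genome + gene set covering all nine effect classes on both strands.
#
# contig "chrT" (length 800):
#   Gp (+): exons 101-160, 201-260; intron 161-200;
#           UTR5 101-110, CDS 111-160 + 201-213 (63 bp), UTR3 214-260
#           CDS codons: ATG AAA TGG (CAT CAC x17 alt) ... TAA
#   Gs (+): single exon 301-400; UTR5 301-310, CDS 311-370 (annotated
#           start codon ATA -> start-gain fixture), UTR3 371-400
#   Gm (-): single exon 501-700; CDS genomic 631-690 (sense ATG CCG CTG
#           CAT... TAA), sense UTR5 genomic 691-700
effect_fixture <- function() {
  contig <- strsplit(filler(800), "")[[1]]
  put <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    contig[at:(at + length(ch) - 1)] <<- ch
  }
  cds_p <- paste(c("ATG", "AAA", "TGG",
                   rep(c("CAT", "CAC"), length.out = 17), "TAA"),
                 collapse = "")
  stopifnot(nchar(cds_p) == 63)
  put("TCTCTCTCTC", 101)                      # Gp UTR5
  put(substr(cds_p, 1, 50), 111)              # Gp CDS part 1
  put(filler(40, "TGCA"), 161)                # Gp intron
  put(substr(cds_p, 51, 63), 201)             # Gp CDS part 2
  put(filler(47, "CT"), 214)                  # Gp UTR3

  cds_s <- paste(c("ATA", rep("CAT", 18), "TAA"), collapse = "")
  put("TCTCTCTCTC", 301)
  put(cds_s, 311)
  put(filler(30, "GA"), 371)

  cds_m_sense <- paste(c("ATG", "CCG", "CTG", rep("CAT", 16), "TAA"),
                       collapse = "")
  sense_m <- paste0("TCCTCCTCCT", cds_m_sense, filler(130, "GA"))
  stopifnot(nchar(sense_m) == 200)
  put(editome::reverse_complement(sense_m), 501)

  genome <- genome_reference(c(chrT = paste(contig, collapse = "")))
  models <- list(
    Gp = gene_model("Gp", "chrT", "+",
                    exons = data.frame(start = c(101, 201), end = c(160, 260)),
                    cds = data.frame(start = c(111, 201), end = c(160, 213))),
    Gs = gene_model("Gs", "chrT", "+",
                    exons = data.frame(start = 301, end = 400),
                    cds = data.frame(start = 311, end = 370)),
    Gm = gene_model("Gm", "chrT", "-",
                    exons = data.frame(start = 501, end = 700),
                    cds = data.frame(start = 631, end = 690)))
  # hand-computed expected effects (genomic alt bases)
  expected <- data.frame(
    pos = c(105, 111, 114, 116, 118, 180, 212, 220,
            313, 687, 682, 695, 550),
    alt = c("G", "G", "G", "G", "A", "C", "C", "G",
            "G", "A", "T", "G", "C"),
    gene = c(rep("Gp", 8), "Gs", "Gm", "Gm", "Gm", "Gm"),
    effect = c("5' UTR", "Loss of start codon", "Non-synonymous coding",
               "Synonymous coding", "Gain of stop codon", "Intron",
               "Loss of stop codon", "3' UTR",
               "Gain of start codon", "Non-synonymous coding",
               "Synonymous coding", "5' UTR", "3' UTR"),
    aa_ref = c(NA, NA, "K", "K", "W", NA, "*", NA, NA, "P", "L", NA, NA),
    aa_alt = c(NA, NA, "E", "K", "*", NA, "S", NA, NA, "S", "L", NA, NA),
    stringsAsFactors = FALSE)
  expected$ref <- genome_base(genome, "chrT", expected$pos)
  list(genome = genome, models = models, expected = expected)
}

# minimal EditSiteTable constructor for filter/annotation tests
make_sites <- function(contig, pos, ref, alt, n = 50L, k = 25L,
                       edit_fwd = NULL, edit_rev = NULL) {
  m <- length(pos)
  k <- rep_len(k, m); n <- rep_len(n, m)
  out <- data.frame(contig = rep_len(contig, m), pos = pos,
                    ref = rep_len(ref, m), alt = rep_len(alt, m),
                    n = n, k = k, f = k / n, k_any = k,
                    pval = rep(1e-6, m), qval = rep(1e-5, m),
                    significant = TRUE, multi_allelic = FALSE,
                    edit_fwd = if (is.null(edit_fwd)) ceiling(k / 2) else rep_len(edit_fwd, m),
                    edit_rev = if (is.null(edit_rev)) floor(k / 2) else rep_len(edit_rev, m))
  class(out) <- c("EditSiteTable", "data.frame")
  out
}

# count table builder: one row per site from named vectors
make_count_table <- function(contig, pos, ref, counts_fwd, counts_rev = NULL,
                             stranded = TRUE) {
  m <- length(pos)
  tab <- data.frame(contig = rep_len(contig, m), pos = pos,
                    ref = rep_len(ref, m))
  for (b in c("A", "C", "G", "T")) {
    tab[[paste0(b, "_fwd")]] <- counts_fwd[[b]] %||% rep(0L, m)
    tab[[paste0(b, "_rev")]] <- if (is.null(counts_rev)) rep(0L, m) else
      counts_rev[[b]] %||% rep(0L, m)
  }
  site_count_table(tab, stranded = stranded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random genome for sequence-level tests
random_genome <- function(seed, lengths = c(contigA = 3000, contigB = 2000)) {
  set.seed(seed)
  genome_reference(vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}
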