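## Synthetic-data generator: a random haploid genome with planted
## multi-exon genes on both strands, a true editome with per-condition
## edit frequencies, and per-sample RNA-/DNA-seq count tables (optionally
## SAM) carrying the statistical structure the analysis assumes:
## binomial edited-read counts, uniform miscalls at the sequencing error
## rate, negative-binomial coverage, per-read strand allocation.

#' Simulation configuration
#'
#' Defaults state the emulated study design: 4 conditions (control plus
#' cold/heat/dark stress) x 4 replicates, sequencing error 0.01 (Phred
#' 20), negative-binomial coverage with mean 69 (the reported median
#' coverage), balanced strand allocation, and edit frequencies in
#' \[0.1, 0.9\] (the 5-95% retained band, bounded away from the floor).
#'
#' @param seed master RNG seed; every stage derives its own stream.
#' @param n_genes number of genes (default 20).
#' @param n_contigs number of contigs genes are spread over (default 2).
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   utr_length_range,intergenic_range integer ranges for gene structure.
#' @param strand_prob probability a gene lies on the forward strand.
#' @param edited_gene_fraction fraction of genes carrying edits
#'   (default 0.5).
#' @param mean_edits_per_gene mean edits per edited gene (>= 1,
#'   default 3).
#' @param intergenic_fraction extra intergenic edits as a fraction of
#'   genic edits (default 0.15).
#' @param edit_freq_range uniform range of true edit frequencies.
#' @param diff_fraction fraction of edited genes that are differentially
#'   edited (default 0.1).
#' @param diff_control_freq,diff_stress_freq true frequencies of
#'   differential genes under control and stress (defaults 0.2 / 0.8).
#' @param coverage_mean,coverage_size negative-binomial coverage mean and
#'   dispersion (defaults 69 and 10).
#' @param error_rate per-read miscall probability (default 0.01).
#' @param read_strand_prob probability a read reports the forward strand.
#' @param conditions,replicates experimental design (defaults: control,
#'   cold, heat, dark x 4).
#' @param duplication plant a 201-bp tandem duplication (uniqueness-filter
#'   fixture)?
#' @param cluster_edits place edits with small geometric gaps (true
#'   clustering) instead of uniformly?
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1, n_genes = 20, n_contigs = 2,
                              exon_count_range = c(1, 4),
                              exon_length_range = c(150, 400),
                              intron_length_range = c(60, 200),
                              utr_length_range = c(24, 90),
                              intergenic_range = c(200, 600),
                              strand_prob = 0.5,
                              edited_gene_fraction = 0.5,
                              mean_edits_per_gene = 3,
                              intergenic_fraction = 0.15,
                              edit_freq_range = c(0.1, 0.9),
                              diff_fraction = 0.1,
                              diff_control_freq = 0.2,
                              diff_stress_freq = 0.8,
                              coverage_mean = 69, coverage_size = 10,
                              error_rate = 0.01, read_strand_prob = 0.5,
                              conditions = c("control", "cold", "heat", "dark"),
                              replicates = 4,
                              duplication = FALSE, cluster_edits = FALSE) {
  stopifnot(error_rate > 0, error_rate < 1, strand_prob >= 0, strand_prob <= 1,
            read_strand_prob >= 0, read_strand_prob <= 1,
            edit_freq_range[1] >= 0, edit_freq_range[2] <= 1,
            mean_edits_per_gene >= 1, n_genes >= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

NONSTOP_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a random genome with planted gene models
#'
#' Genes are multi-exon, on both strands, with valid CDS (ATG start, TAA
#' stop, length divisible by 3, no internal in-frame stops) flanked by
#' UTRs.  With `duplication = TRUE` a 201-bp segment of the first gene is
#' copied verbatim into the tail of its contig (a planted
#' uniqueness-filter failure).
#'
#' @param config a [simulation_config()].
#' @param fasta_path,gff_path optional output paths; written when given.
#' @return list: `genome` (`GenomeReference`), `gene_models` (named
#'   list), `duplicated_region` (or NULL).
#' @export
generate_reference <- function(config, fasta_path = NULL, gff_path = NULL) {
  set.seed(derive_seed(config$seed, "reference"))
  rint <- function(rg) if (rg[1] == rg[2]) rg[1] else sample(rg[1]:rg[2], 1)

  contig_parts <- rep(list(character(0)), config$n_contigs)
  contig_off <- rep(0L, config$n_contigs)
  names(contig_parts) <- paste0("contig", seq_len(config$n_contigs))
  models <- list()

  for (gi in seq_len(config$n_genes)) {
    n_ex <- rint(config$exon_count_range)
    ex_lens <- vapply(seq_len(n_ex), function(i) rint(config$exon_length_range),
                      numeric(1))
    in_lens <- if (n_ex > 1) {
      vapply(seq_len(n_ex - 1), function(i) rint(config$intron_length_range),
             numeric(1))
    } else numeric(0)
    exonic <- sum(ex_lens)
    utr5 <- rint(config$utr_length_range)
    utr3 <- rint(config$utr_length_range)
    ## keep a CDS of at least 30 bp: shrink UTRs if the exons are short
    spare <- exonic - 30L - utr5 - utr3
    if (spare < 0) {
      utr5 <- max(3L, utr5 + floor(spare / 2))
      utr3 <- max(3L, exonic - 30L - utr5)
    }
    cds_len <- exonic - utr5 - utr3
    cds_len <- cds_len - (cds_len %% 3)
    if (cds_len < 30) stopf("exon lengths too short for a CDS; widen exon_length_range")
    utr3 <- exonic - utr5 - cds_len
    cds <- paste(c("ATG", sample(NONSTOP_CODONS, cds_len / 3 - 2, replace = TRUE),
                   "TAA"), collapse = "")
    spliced <- paste0(rand_dna(utr5), cds, rand_dna(utr3))

    ## local (sense) coordinates of exons within the unspliced gene
    ex_start_local <- cumsum(c(1, head(ex_lens, -1) + in_lens))
    ex_end_local <- ex_start_local + ex_lens - 1
    glen <- sum(ex_lens) + sum(in_lens)
    ## unspliced sense sequence: exon chunks interleaved with introns
    sp_off <- cumsum(c(0, head(ex_lens, -1)))
    chunks <- character(0)
    for (e in seq_len(n_ex)) {
      chunks <- c(chunks, substr(spliced, sp_off[e] + 1, sp_off[e] + ex_lens[e]))
      if (e < n_ex) chunks <- c(chunks, rand_dna(in_lens[e]))
    }
    sense_seq <- paste(chunks, collapse = "")

    ## spliced CDS range -> local sense intervals
    cds_sp <- c(utr5 + 1, utr5 + cds_len)
    cds_local <- list()
    for (e in seq_len(n_ex)) {
      sp_a <- sp_off[e] + 1; sp_b <- sp_off[e] + ex_lens[e]
      a <- max(sp_a, cds_sp[1]); b <- min(sp_b, cds_sp[2])
      if (a <= b) {
        cds_local[[length(cds_local) + 1]] <-
          c(ex_start_local[e] + (a - sp_a), ex_start_local[e] + (b - sp_a))
      }
    }
    strand <- if (runif(1) < config$strand_prob) "+" else "-"
    ci <- ((gi - 1) %% config$n_contigs) + 1
    gap <- rint(config$intergenic_range)
    gstart <- contig_off[ci] + gap + 1

    if (strand == "+") {
      gseq <- sense_seq
      ex_g <- data.frame(start = gstart + ex_start_local - 1,
                         end = gstart + ex_end_local - 1)
      cds_g <- data.frame(
        start = gstart + vapply(cds_local, `[`, numeric(1), 1) - 1,
        end = gstart + vapply(cds_local, `[`, numeric(1), 2) - 1)
    } else {
      gseq <- reverse_complement(sense_seq)
      ex_g <- data.frame(start = gstart + glen - ex_end_local,
                         end = gstart + glen - ex_start_local)
      cds_g <- data.frame(
        start = gstart + glen - vapply(cds_local, `[`, numeric(1), 2),
        end = gstart + glen - vapply(cds_local, `[`, numeric(1), 1))
    }
    gid <- sprintf("gene%03d", gi)
    models[[gid]] <- gene_model(gid, names(contig_parts)[ci], strand, ex_g, cds_g)
    contig_parts[[ci]] <- c(contig_parts[[ci]], rand_dna(gap), gseq)
    contig_off[ci] <- contig_off[ci] + gap + glen
  }
  dup <- NULL
  for (ci in seq_len(config$n_contigs)) {
    tailgap <- rand_dna(rint(config$intergenic_range))
    if (config$duplication && ci == 1) {
      g1 <- models[[1]]
      a <- g1$start + max(0, (g1$end - g1$start) %/% 2 - 100)
      seqs <- paste(contig_parts[[1]], collapse = "")
      dupseq <- substr(seqs, a, a + 200)
      dup <- list(contig = names(contig_parts)[1], src_start = a,
                  src_end = a + 200L, dest_start = contig_off[1] + nchar(tailgap) + 1L)
      tailgap <- paste0(tailgap, dupseq, rand_dna(50))
    }
    contig_parts[[ci]] <- c(contig_parts[[ci]], tailgap)
  }
  contigs <- vapply(contig_parts, paste, character(1), collapse = "")
  genome <- genome_reference(contigs)
  if (!is.null(fasta_path)) write_genome_fasta(genome, fasta_path)
  if (!is.null(gff_path)) write_gene_models_gff3(models, gff_path)
  list(genome = genome, gene_models = models, duplicated_region = dup)
}

#' Write a genome as FASTA
#'
#' @param genome a `GenomeReference`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/exon/CDS features with `Parent` pointing at the gene.
#'
#' @param gene_models named list of `GeneModel`s.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  lines <- "##gff-version 3"
  for (g in gene_models) {
    lines <- c(lines, sprintf("%s\teditome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$contig, g$start, g$end, g$strand, g$gene_id))
    for (i in seq_len(nrow(g$exons))) {
      lines <- c(lines, sprintf("%s\teditome\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                g$contig, g$exons$start[i], g$exons$end[i],
                                g$strand, g$gene_id))
    }
    if (nrow(g$cds)) {
      ord <- if (g$strand == "+") seq_len(nrow(g$cds)) else rev(seq_len(nrow(g$cds)))
      lens <- g$cds$end - g$cds$start + 1L
      phase <- (3L - (cumsum(c(0L, lens[ord][-nrow(g$cds)])) %% 3L)) %% 3L
      for (j in seq_along(ord)) {
        i <- ord[j]
        lines <- c(lines, sprintf("%s\teditome\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                                  g$contig, g$cds$start[i], g$cds$end[i],
                                  g$strand, phase[j], g$gene_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a true editome
#'
#' Plants edit sites in genes (and optionally intergenic space), avoiding
#' homopolymer runs and intron edges so the planted truth survives the
#' artefact filters.  A configured fraction of edited genes receives
#' condition-shifted frequencies (the differential-editing truth); all
#' other sites keep one frequency across conditions.
#'
#' @param config a [simulation_config()].
#' @param genome a `GenomeReference`.
#' @param gene_models named list of `GeneModel`s.
#' @param allow_violations place edits without avoiding masked positions
#'   and intron edges (for filter fixtures).
#' @return data.frame of class `TruthTable`: `contig`, `pos`, `gene_id`
#'   (`"intergenic"` where applicable), `ref`, `alt`, `differential`, and
#'   one `f_<condition>` column per condition.
#' @export
generate_editome <- function(config, genome, gene_models,
                             allow_violations = FALSE) {
  set.seed(derive_seed(config$seed, "editome"))
  mask <- mask_homopolymers(genome, 4)
  fcfg <- filter_config()
  n_edited <- max(1, round(length(gene_models) * config$edited_gene_fraction))
  edited_genes <- sample(names(gene_models), n_edited)
  n_diff <- round(n_edited * config$diff_fraction)
  diff_genes <- if (n_diff > 0) sample(edited_genes, n_diff) else character(0)

  rows <- list()
  for (gid in edited_genes) {
    g <- gene_models[[gid]]
    cand <- g$start:g$end
    if (!allow_violations) {
      cand <- cand[!is_masked(mask, rep(g$contig, length(cand)), cand)]
      edge_ok <- intron_edge_filter(rep(g$contig, length(cand)), cand,
                                    gene_models[gid], fcfg)
      cand <- cand[edge_ok]
    }
    k <- min(length(cand), 1 + rpois(1, config$mean_edits_per_gene - 1))
    if (k < 1) next
    pos <- if (config$cluster_edits && length(cand) > 10) {
      start <- cand[sample.int(max(1, length(cand) - 10 * k), 1)]
      p <- cumsum(c(start, 1 + rgeom(k - 1, 0.4)))
      intersect(p, cand)[seq_len(min(k, length(intersect(p, cand))))]
    } else {
      sort(sample(cand, k))
    }
    if (!length(pos)) next
    ref <- genome_base(genome, g$contig, pos)
    ok <- ref %in% BASES
    pos <- pos[ok]; ref <- ref[ok]
    if (!length(pos)) next
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    is_diff <- gid %in% diff_genes
    f0 <- if (is_diff) rep(config$diff_control_freq, length(pos)) else
      runif(length(pos), config$edit_freq_range[1], config$edit_freq_range[2])
    d <- data.frame(contig = g$contig, pos = pos, gene_id = gid, ref = ref,
                    alt = alt, differential = is_diff)
    for (cond in config$conditions) {
      d[[paste0("f_", cond)]] <-
        if (is_diff && cond != config$conditions[1]) config$diff_stress_freq else f0
    }
    rows[[length(rows) + 1]] <- d
  }
  ## intergenic edits
  n_inter <- round(sum(vapply(rows, nrow, integer(1))) * config$intergenic_fraction)
  if (n_inter > 0) {
    genic <- rep(FALSE, sum(genome$lengths))
    offs <- cumsum(c(0, genome$lengths[-length(genome$lengths)]))
    names(offs) <- names(genome$contigs)
    for (g in gene_models) genic[offs[g$contig] + (g$start:g$end)] <- TRUE
    pool <- which(!genic)
    pick <- sort(sample(pool, min(n_inter, length(pool))))
    ct_idx <- findInterval(pick - 1, offs)
    ct <- names(genome$contigs)[ct_idx]
    pos <- as.integer(pick - offs[ct_idx])
    ref <- genome_base(genome, ct, pos)
    ok <- ref %in% BASES & !is_masked(mask, ct, pos)
    if (any(ok)) {
      ct <- ct[ok]; pos <- pos[ok]; ref <- ref[ok]
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
      f0 <- runif(length(pos), config$edit_freq_range[1], config$edit_freq_range[2])
      d <- data.frame(contig = ct, pos = pos, gene_id = "intergenic", ref = ref,
                      alt = alt, differential = FALSE)
      for (cond in config$conditions) d[[paste0("f_", cond)]] <- f0
      rows[[length(rows) + 1]] <- d
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  out <- out[!duplicated(paste(out$contig, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TruthTable", "data.frame")
  out
}

## multinomial split of an error-count vector over three alternatives
split3 <- function(err) {
  x1 <- rbinom(length(err), err, 1 / 3)
  x2 <- rbinom(length(err), err - x1, 1 / 2)
  cbind(x1, x2, err - x1 - x2)
}

#' Simulate a per-sample site count table
#'
#' At a true edit site with condition frequency f, edited reads are
#' Binomial(n, f); every read is further miscalled uniformly to one of
#' the three other bases with probability `error_rate`; each read
#' reports the forward strand with probability `read_strand_prob`.
#' Coverage is negative-binomial.  DNA-seq tables are obtained with
#' `truth = NULL` (the genome itself is unedited).
#'
#' @param config a [simulation_config()].
#' @param genome a `GenomeReference`.
#' @param truth a `TruthTable` from [generate_editome()], or `NULL` for
#'   a pure-error (DNA-seq-like) sample.
#' @param condition condition name (selects the `f_<condition>` truth
#'   column); used in the RNG stream and sample id.
#' @param replicate replicate number.
#' @param positions optional data.frame (`contig`, `pos`) restricting the
#'   simulated positions (default: every genomic position).
#' @param coverage_mean override of `config$coverage_mean`.
#' @return a `SiteCountTable` (`sample_id = "<condition>_rep<k>"`).
#' @export
simulate_counts <- function(config, genome, truth = NULL,
                            condition = "control", replicate = 1,
                            positions = NULL, coverage_mean = NULL) {
  set.seed(derive_seed(config$seed,
                       paste("counts", condition, replicate,
                             if (is.null(truth)) "dna" else "rna")))
  mu <- coverage_mean %||% config$coverage_mean
  if (is.null(positions)) {
    positions <- do.call(rbind, lapply(names(genome$contigs), function(ct)
      data.frame(contig = ct, pos = seq_len(genome$lengths[[ct]]))))
  }
  ref <- genome_base(genome, positions$contig, positions$pos)
  keep <- ref %in% BASES
  positions <- positions[keep, , drop = FALSE]
  ref <- ref[keep]
  N <- nrow(positions)
  n <- rnbinom(N, mu = mu, size = config$coverage_size)

  f <- rep(0, N)
  alt <- rep(NA_character_, N)
  if (!is.null(truth)) {
    idx <- match(paste(positions$contig, positions$pos),
                 paste(truth$contig, truth$pos))
    hit <- !is.na(idx)
    fcol <- paste0("f_", condition)
    if (!fcol %in% names(truth)) stopf("truth table lacks column %s", fcol)
    f[hit] <- truth[[fcol]][idx[hit]]
    alt[hit] <- truth$alt[idx[hit]]
  }
  k_edit <- integer(N)
  has_f <- f > 0 & n > 0
  k_edit[has_f] <- rbinom(sum(has_f), n[has_f], f[has_f])

  counts <- matrix(0L, N, 4, dimnames = list(NULL, BASES))
  ref_idx <- match(ref, BASES)
  cR <- n - k_edit
  errR <- rbinom(N, cR, config$error_rate)
  eR <- split3(errR)
  counts[cbind(seq_len(N), ref_idx)] <- cR - errR
  others <- t(vapply(ref_idx, function(i) setdiff(1:4, i), integer(3)))
  for (j in 1:3) {
    counts[cbind(seq_len(N), others[, j])] <-
      counts[cbind(seq_len(N), others[, j])] + eR[, j]
  }
  ed <- which(k_edit > 0)
  if (length(ed)) {
    errA <- rbinom(length(ed), k_edit[ed], config$error_rate)
    eA <- split3(errA)
    alt_idx <- match(alt[ed], BASES)
    counts[cbind(ed, alt_idx)] <- counts[cbind(ed, alt_idx)] + k_edit[ed] - errA
    for (j in seq_along(ed)) {
      oth <- setdiff(1:4, alt_idx[j])
      counts[ed[j], oth] <- counts[ed[j], oth] + eA[j, ]
    }
  }
  fwd <- matrix(rbinom(length(counts), as.vector(counts),
                       config$read_strand_prob), N, 4)
  rev <- counts - fwd
  tab <- data.frame(contig = positions$contig, pos = positions$pos, ref = ref)
  for (j in 1:4) tab[[paste0(BASES[j], "_fwd")]] <- fwd[, j]
  for (j in 1:4) tab[[paste0(BASES[j], "_rev")]] <- rev[, j]
  tab <- tab[n > 0, , drop = FALSE]
  site_count_table(tab, stranded = TRUE,
                   sample_id = paste0(condition, "_rep", replicate))
}

#' Simulate a SAM file with a matching, independently tallied count table
#'
#' Emits single-end reads copied from the genome (optionally with
#' multimappers, i.e. mapping quality 0, and exact PCR duplicates) and
#' computes the count table those reads imply under the counting
#' contract by direct arithmetic: mapq-0 reads and duplicate keys are
#' dropped, each surviving read contributes its bases at offsets
#' `[end_trim + 1, read_len - end_trim]`.  The expected table is the
#' pileup module's round-trip oracle.
#'
#' @param config a [simulation_config()] (seed source).
#' @param genome a `GenomeReference`.
#' @param n_reads number of primary reads (default 200).
#' @param read_len read length (default 50).
#' @param end_trim trim used for the expected table (default 9).
#' @param frac_multimap fraction of reads flagged mapq 0 (default 0.1).
#' @param frac_duplicate fraction of reads duplicated once (default 0.1).
#' @param sam_path optional path to write the SAM text.
#' @return list: `sam_lines`, `expected` (a `SiteCountTable`).
#' @export
simulate_sam <- function(config, genome, n_reads = 200, read_len = 50,
                         end_trim = 9, frac_multimap = 0.1,
                         frac_duplicate = 0.1, sam_path = NULL) {
  set.seed(derive_seed(config$seed, "sam"))
  cts <- names(genome$contigs)[genome$lengths >= read_len]
  ct <- sample(cts, n_reads, replace = TRUE)
  start <- vapply(ct, function(c)
    sample.int(genome$lengths[[c]] - read_len + 1L, 1), integer(1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  mapq <- ifelse(runif(n_reads) < frac_multimap, 0L, 60L)
  reads <- data.frame(qname = sprintf("read%04d", seq_len(n_reads)),
                      contig = ct, start = start, strand = strand, mapq = mapq)
  ndup <- round(n_reads * frac_duplicate)
  if (ndup > 0) {
    dup <- reads[sample.int(n_reads, ndup), , drop = FALSE]
    dup$qname <- paste0(dup$qname, "_dup")
    reads <- rbind(reads, dup)
  }
  reads$seq <- vapply(seq_len(nrow(reads)), function(i)
    genome_seq(genome, reads$contig[i], reads$start[i],
               reads$start[i] + read_len - 1L), character(1))
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome$contigs), genome$lengths),
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            reads$qname, ifelse(reads$strand == "-", 16L, 0L), reads$contig,
            reads$start, reads$mapq, read_len, reads$seq))

  ## expected table by direct arithmetic
  kept <- reads[reads$mapq > 0L, , drop = FALSE]
  kept <- kept[!duplicated(paste(kept$contig, kept$start, kept$strand)), ,
               drop = FALSE]
  offs <- (end_trim + 1L):(read_len - end_trim)
  ect <- rep(kept$contig, each = length(offs))
  eps <- as.integer(rep(kept$start, each = length(offs)) +
                      rep(offs, nrow(kept)) - 1L)
  est <- rep(ifelse(kept$strand == "-", "rev", "fwd"), each = length(offs))
  ebs <- genome_base(genome, ect, eps)
  keep <- ebs %in% BASES
  ect <- ect[keep]; eps <- eps[keep]; est <- est[keep]; ebs <- ebs[keep]
  id <- paste(ect, eps)
  uid <- unique(id)
  cnt <- table(factor(id, levels = uid),
               factor(match(paste0(ebs, "_", est), COUNT_COLS), levels = 1:8))
  first <- match(uid, id)
  tab <- data.frame(contig = ect[first], pos = eps[first], ref = ebs[first])
  for (j in 1:8) tab[[COUNT_COLS[j]]] <- as.integer(cnt[, j])
  expected <- site_count_table(tab, stranded = TRUE, sample_id = "sam_expected")
  if (!is.null(sam_path)) writeLines(sam_lines, sam_path)
  list(sam_lines = sam_lines, expected = expected)
}

#' Write a truth table TSV
#'
#' @param truth a `TruthTable`.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Writes genome FASTA, gene-model GFF3, truth TSV, one RNA-seq count
#' table per condition x replicate (restricted to truth positions plus a
#' margin of background positions for realism at pipeline scale), a
#' pooled table over the whole genome, and a DNA-seq table.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created).
#' @return invisibly, a list of the written paths and the in-memory
#'   objects.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(config,
                            fasta_path = file.path(dir, "genome.fa"),
                            gff_path = file.path(dir, "genes.gff3"))
  truth <- generate_editome(config, ref$genome, ref$gene_models)
  write_truth_table(truth, file.path(dir, "truth.tsv"))
  ## pooled calling run simulated directly at the calling depth; the mean
  ## frequency across conditions is what pooling the libraries realises
  truth$f_pooled <- rowMeans(truth[paste0("f_", config$conditions)])
  sample_paths <- character(0)
  info <- list()
  for (cond in config$conditions) {
    for (r in seq_len(config$replicates)) {
      tab <- simulate_counts(config, ref$genome, truth, cond, r,
                             positions = truth[c("contig", "pos")])
      p <- file.path(dir, sprintf("counts_%s_rep%d.tsv", cond, r))
      write_count_table(tab, p)
      sample_paths <- c(sample_paths, p)
      info[[length(info) + 1]] <- data.frame(
        sample_id = attr(tab, "sample_id"), condition = cond, replicate = r,
        path = p)
    }
  }
  pooled <- simulate_counts(config, ref$genome, truth, "pooled", 1)
  write_count_table(pooled, file.path(dir, "counts_pooled.tsv"))
  dna <- simulate_counts(config, ref$genome, NULL, "dna", 1)
  write_count_table(dna, file.path(dir, "counts_dna.tsv"))
  sample_info <- do.call(rbind, info)
  write.table(sample_info, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, genome = ref$genome, gene_models = ref$gene_models,
                 truth = truth, sample_info = sample_info))
}
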