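## Per-site, per-strand base counts and the counting contract:
## read-end trimming, unique-mapper-only, per-replicate de-duplication and
## homopolymer masking.

COUNT_COLS <- c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                "A_rev", "C_rev", "G_rev", "T_rev")

empty_count_table <- function(stranded = TRUE, sample_id = NA_character_) {
  tab <- data.frame(contig = character(0), pos = integer(0), ref = character(0))
  for (cc in COUNT_COLS) tab[[cc]] <- integer(0)
  site_count_table(tab, stranded = stranded, sample_id = sample_id)
}

#' Construct a site count table
#'
#' The canonical per-sample container: one row per covered genomic
#' position with per-base, per-strand read counts.  Unstranded data keep
#' all counts in the `*_fwd` columns with `stranded = FALSE`.
#'
#' @param tab data.frame with columns `contig`, `pos`, `ref` and the eight
#'   count columns `A_fwd` ... `T_rev`.
#' @param stranded logical; whether per-strand counts are meaningful.
#' @param sample_id optional sample label.
#' @return the table with class `SiteCountTable`.
#' @export
site_count_table <- function(tab, stranded = TRUE, sample_id = NA_character_) {
  need <- c("contig", "pos", "ref", COUNT_COLS)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("count table missing column(s): %s",
                          paste(miss, collapse = ", "))
  tab <- tab[order(tab$contig, tab$pos), need, drop = FALSE]
  rownames(tab) <- NULL
  for (cc in COUNT_COLS) tab[[cc]] <- as.integer(tab[[cc]])
  if (any(vapply(tab[COUNT_COLS], function(x) any(x < 0), logical(1)))) {
    stopf("negative counts in count table")
  }
  structure(tab, stranded = stranded, sample_id = sample_id,
            class = c("SiteCountTable", "data.frame"))
}

#' Total coverage per site
#'
#' @param tab a `SiteCountTable`.
#' @return integer vector, one per row.
#' @export
site_coverage <- function(tab) {
  as.integer(rowSums(as.matrix(tab[COUNT_COLS])))
}

## n x 4 matrix of per-base totals (both strands)
base_totals <- function(tab) {
  m <- as.matrix(tab[COUNT_COLS])
  m[, 1:4, drop = FALSE] + m[, 5:8, drop = FALSE]
}

#' Mask homopolymer runs
#'
#' A position is masked iff it lies inside a maximal run of at least
#' `min_run` identical reference bases; `N` never forms a run.
#'
#' @param genome a `GenomeReference`.
#' @param min_run minimum run length (>= 2); default 4.
#' @return object of class `HomopolymerMask`: per-contig integer position
#'   vectors plus the `min_run` used.
#' @export
mask_homopolymers <- function(genome, min_run = 4) {
  if (min_run < 2) stopf("min_run must be >= 2")
  pos <- lapply(names(genome$contigs), function(ct) {
    r <- rle(strsplit(genome$contigs[[ct]], "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_run & r$values != "N"
    if (!any(keep)) return(integer(0))
    unlist(mapply(seq.int, starts[keep], ends[keep], SIMPLIFY = FALSE),
           use.names = FALSE)
  })
  names(pos) <- names(genome$contigs)
  structure(list(positions = pos, min_run = min_run),
            class = "HomopolymerMask")
}

#' @export
print.HomopolymerMask <- function(x, ...) {
  cat(sprintf("HomopolymerMask: min run %d, %d masked position(s)\n",
              x$min_run, sum(lengths(x$positions))))
  invisible(x)
}

is_masked <- function(mask, contig, pos) {
  if (is.null(mask)) return(rep(FALSE, length(pos)))
  out <- logical(length(pos))
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- pos[i] %in% (mask$positions[[ct]] %||% integer(0))
  }
  out
}

## ---- SAM handling ---------------------------------------------------------

## minimal plain-text SAM reader; returns one data.frame row per mapped record
read_sam <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(0), flag = integer(0),
                      contig = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      seq = character(0), qual = character(0),
                      nh = integer(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11
  if (any(short)) stopf("malformed SAM record at data line %d", which(short)[1])
  get <- function(i) vapply(f, `[`, character(1), i)
  nh <- vapply(f, function(x) {
    t <- grep("^NH:i:", x[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("^NH:i:", "", t[1])) else 1L
  }, integer(1))
  df <- data.frame(qname = get(1), flag = as.integer(get(2)),
                   contig = get(3), pos = as.integer(get(4)),
                   mapq = as.integer(get(5)), cigar = get(6),
                   rnext = get(7), pnext = as.integer(get(8)),
                   seq = toupper(get(10)), qual = get(11), nh = nh)
  df[bitwAnd(df$flag, 4L) == 0L & df$contig != "*", , drop = FALSE]
}

#' De-duplicate alignments
#'
#' Keeps one representative per (contig, start, mate start, strand) key —
#' unpaired reads are keyed on (contig, start, strand) — removing PCR
#' duplicates on a per-replicate basis.
#'
#' @param aln alignment data.frame as returned by the internal SAM reader
#'   (columns `flag`, `contig`, `pos`, `rnext`, `pnext`).
#' @return the alignment data.frame with duplicates removed.
#' @export
deduplicate_alignments <- function(aln) {
  if (!nrow(aln)) return(aln)
  strand <- ifelse(bitwAnd(aln$flag, 16L) != 0L, "-", "+")
  paired <- bitwAnd(aln$flag, 1L) != 0L
  mate_ct <- ifelse(aln$rnext == "=", aln$contig, aln$rnext)
  key <- ifelse(paired,
                paste(aln$contig, aln$pos, mate_ct, aln$pnext, strand),
                paste(aln$contig, aln$pos, strand))
  aln[!duplicated(key), , drop = FALSE]
}

## expand one CIGAR into aligned (ref position, query offset) pairs.
## Returns NULL for unsupported operations.
cigar_aligned_pairs <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  chars <- sub("^\\d+", "", ops)
  if (any(!chars %in% c("M", "=", "X", "I", "D", "N", "S", "H", "P"))) {
    return(NULL)
  }
  rp <- pos; qp <- 1L
  refs <- integer(0); qoffs <- integer(0)
  for (i in seq_along(chars)) {
    L <- lens[i]
    switch(chars[i],
           "M" = , "=" = , "X" = {
             refs <- c(refs, rp:(rp + L - 1L))
             qoffs <- c(qoffs, qp:(qp + L - 1L))
             rp <- rp + L; qp <- qp + L
           },
           "I" = , "S" = { qp <- qp + L },
           "D" = , "N" = { rp <- rp + L },
           NULL)
  }
  list(ref = refs, qoff = qoffs, qlen = qp - 1L)
}

#' Pileup base counts from a SAM file
#'
#' Reproduces the counting contract: each read contributes its aligned
#' base calls only at read offsets `[end_trim + 1, read length - end_trim]`
#' (sequencing errors concentrate on read ends); reads flagged non-unique
#' (mapping quality 0 or an `NH` tag > 1) contribute nothing when
#' `unique_only`; PCR duplicates are collapsed; homopolymer-masked
#' positions are absent from the output.  Insertions and deletions never
#' contribute to substitution counts.
#'
#' @param sam_path path to a plain-text SAM file.
#' @param genome a `GenomeReference` (provides reference bases).
#' @param mask optional [mask_homopolymers()] result.
#' @param end_trim bases ignored at each read end (default 9).
#' @param unique_only drop non-uniquely mapped reads (default `TRUE`).
#' @param dedup de-duplicate reads first (default `TRUE`).
#' @param min_base_quality optional minimum Phred base quality (default 0 =
#'   off, matching the calling model's contract).
#' @param sample_id label stored on the result.
#' @return a `SiteCountTable`.  The attribute `"skipped_records"` counts
#'   reads dropped for unsupported CIGAR operations.
#' @export
pileup_from_sam <- function(sam_path, genome, mask = NULL, end_trim = 9,
                            unique_only = TRUE, dedup = TRUE,
                            min_base_quality = 0,
                            sample_id = basename(sam_path)) {
  aln <- read_sam(sam_path)
  if (unique_only && nrow(aln)) {
    aln <- aln[aln$mapq > 0L & aln$nh <= 1L, , drop = FALSE]
  }
  if (dedup) aln <- deduplicate_alignments(aln)
  skipped <- 0L
  ct <- character(0); ps <- integer(0); bs <- character(0); st <- character(0)
  for (i in seq_len(nrow(aln))) {
    ap <- cigar_aligned_pairs(aln$cigar[i], aln$pos[i])
    if (is.null(ap)) { skipped <- skipped + 1L; next }
    keep <- ap$qoff > end_trim & ap$qoff <= ap$qlen - end_trim
    if (min_base_quality > 0 && aln$qual[i] != "*") {
      q <- utf8ToInt(aln$qual[i]) - 33L
      keep <- keep & q[ap$qoff] >= min_base_quality
    }
    if (!any(keep)) next
    bases <- substring(aln$seq[i], ap$qoff[keep], ap$qoff[keep])
    ok <- bases %in% BASES
    if (!any(ok)) next
    ct <- c(ct, rep(aln$contig[i], sum(ok)))
    ps <- c(ps, ap$ref[keep][ok])
    bs <- c(bs, bases[ok])
    st <- c(st, rep(if (bitwAnd(aln$flag[i], 16L) != 0L) "rev" else "fwd", sum(ok)))
  }
  if (!length(ps)) {
    out <- empty_count_table(sample_id = sample_id)
    attr(out, "skipped_records") <- skipped
    return(out)
  }
  drop <- is_masked(mask, ct, ps)
  ct <- ct[!drop]; ps <- ps[!drop]; bs <- bs[!drop]; st <- st[!drop]
  if (!length(ps)) {
    out <- empty_count_table(sample_id = sample_id)
    attr(out, "skipped_records") <- skipped
    return(out)
  }
  id <- paste(ct, ps)
  uid <- unique(id)
  colid <- match(paste0(bs, "_", st), COUNT_COLS)
  cnt <- table(factor(id, levels = uid), factor(colid, levels = 1:8))
  first <- match(uid, id)
  tab <- data.frame(contig = ct[first], pos = ps[first],
                    ref = genome_base(genome, ct[first], ps[first]))
  for (j in 1:8) tab[[COUNT_COLS[j]]] <- as.integer(cnt[, j])
  tab <- tab[tab$ref != "N", , drop = FALSE]
  out <- site_count_table(tab, stranded = TRUE, sample_id = sample_id)
  attr(out, "skipped_records") <- skipped
  out
}

## ---- count-table I/O ------------------------------------------------------

#' Read a per-site count table (TSV)
#'
#' Dialect: tab-separated with a header; columns `contig`, `pos` (1-based),
#' `ref`, and either the eight stranded columns `A_fwd` ... `T_rev` or the
#' four unstranded columns `A`, `C`, `G`, `T` (in which case downstream
#' strand-bias filtering reports "not evaluable").
#'
#' @param path TSV path.
#' @param genome optional `GenomeReference`; rows whose `ref` disagrees
#'   with the genome raise an error.
#' @param sample_id label stored on the result.
#' @return a `SiteCountTable`.
#' @export
read_count_table <- function(path, genome = NULL, sample_id = basename(path)) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  if (file.size(path) == 0) return(empty_count_table(sample_id = sample_id))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(tab)) return(empty_count_table(sample_id = sample_id))
  stranded <- all(COUNT_COLS %in% names(tab))
  if (!stranded) {
    if (!all(BASES %in% names(tab))) {
      stopf("count table %s lacks both stranded (A_fwd..T_rev) and unstranded (A,C,G,T) columns", path)
    }
    for (b in BASES) {
      tab[[paste0(b, "_fwd")]] <- tab[[b]]
      tab[[paste0(b, "_rev")]] <- 0L
    }
  }
  tab$ref <- toupper(tab$ref)
  if (!is.null(genome)) {
    gb <- genome_base(genome, tab$contig, tab$pos)
    bad <- which(gb != tab$ref)
    if (length(bad)) {
      stopf("row %d of %s: ref base '%s' disagrees with genome '%s' at %s:%d",
            bad[1], path, tab$ref[bad[1]], gb[bad[1]],
            tab$contig[bad[1]], tab$pos[bad[1]])
    }
  }
  site_count_table(tab, stranded = stranded, sample_id = sample_id)
}

#' Write a count table TSV
#'
#' @param tab a `SiteCountTable`.
#' @param path output path.
#' @export
write_count_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge count tables position-wise
#'
#' Sums counts across samples at each position (the pooled table used for
#' edit calling).
#'
#' @param tables list of `SiteCountTable`s.
#' @return a pooled `SiteCountTable` (`sample_id = "pooled"`).
#' @export
merge_count_tables <- function(tables) {
  tables <- tables[vapply(tables, nrow, integer(1)) > 0]
  if (!length(tables)) return(empty_count_table(sample_id = "pooled"))
  all <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)))
  key <- paste(all$contig, all$pos)
  ref_by_key <- tapply(all$ref, key, function(r) length(unique(r)))
  if (any(ref_by_key > 1)) stopf("inconsistent reference bases across samples")
  m <- rowsum(as.matrix(all[COUNT_COLS]), key)
  first <- match(rownames(m), key)
  tab <- data.frame(contig = all$contig[first], pos = all$pos[first],
                    ref = all$ref[first])
  tab[COUNT_COLS] <- as.data.frame(m)
  site_count_table(tab,
                   stranded = all(vapply(tables, attr, logical(1), "stranded")),
                   sample_id = "pooled")
}
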