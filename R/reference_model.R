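## Genome and gene-model containers.
##
## Coordinates are 1-based inclusive throughout the package (the native
## GFF3 / R / Biostrings convention); file readers therefore never shift.

#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a `GenomeReference`: a set of uppercase
#' contig sequences indexed by the first word of each header.
#'
#' @param fasta_path path to a FASTA file.
#' @return an object of class `GenomeReference` with elements `contigs`
#'   (named character vector of uppercase sequences) and `lengths`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' g$lengths
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stopf("FASTA file not found: %s", fasta_path)
  ss <- Biostrings::readDNAStringSet(fasta_path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) stopf("duplicate contig ids in %s", fasta_path)
  contigs <- toupper(as.character(ss))
  names(contigs) <- nm
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stopf("contig '%s' contains characters outside A/C/G/T/N", nm[bad][1])
  }
  structure(list(contigs = contigs, lengths = nchar(contigs)),
            class = "GenomeReference")
}

#' Construct a genome reference from in-memory sequences
#'
#' @param contigs named character vector of contig sequences.
#' @return a `GenomeReference`.
#' @export
genome_reference <- function(contigs) {
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stopf("contigs must be a named character vector")
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) stopf("contig '%s' contains invalid characters",
                      names(contigs)[bad][1])
  structure(list(contigs = contigs, lengths = nchar(contigs)),
            class = "GenomeReference")
}

#' @export
print.GenomeReference <- function(x, ...) {
  cat(sprintf("GenomeReference: %d contig(s), %s bp total\n",
              length(x$contigs), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

check_contig <- function(genome, contig) {
  if (!contig %in% names(genome$contigs)) {
    stopf("contig '%s' not present in genome", contig)
  }
}

#' Extract genome sequence
#'
#' @param genome a `GenomeReference`.
#' @param contig contig id.
#' @param start,end 1-based inclusive coordinates.
#' @return character scalar.
#' @export
genome_seq <- function(genome, contig, start, end) {
  check_contig(genome, contig)
  len <- genome$lengths[[contig]]
  if (start < 1 || end > len || start > end) {
    stopf("coordinates %d-%d outside contig '%s' (length %d)",
          start, end, contig, len)
  }
  substr(genome$contigs[[contig]], start, end)
}

#' Look up single reference bases (vectorised)
#'
#' @inheritParams genome_seq
#' @param pos integer vector of 1-based positions.
#' @return character vector of bases.
#' @export
genome_base <- function(genome, contig, pos) {
  contig <- rep_len(contig, length(pos))
  out <- character(length(pos))
  for (ct in unique(contig)) {
    check_contig(genome, ct)
    i <- which(contig == ct)
    if (any(pos[i] < 1 | pos[i] > genome$lengths[[ct]])) {
      stopf("position outside contig '%s'", ct)
    }
    out[i] <- substring(genome$contigs[[ct]], pos[i], pos[i])
  }
  out
}

## ---- gene models ----------------------------------------------------------

norm_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- data.frame(start = as.integer(df$start), end = as.integer(df$end))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$end < df$start)) stopf("interval with end < start")
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    stopf("overlapping intervals in gene structure")
  }
  df
}

intervals_len <- function(df) if (nrow(df) == 0) 0L else sum(df$end - df$start + 1L)

## gaps between consecutive sorted intervals
gaps_between <- function(df) {
  if (nrow(df) < 2) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = df$end[-nrow(df)] + 1L, end = df$start[-1] - 1L)
}

## positions of `ivs` (sorted, non-overlapping) below/above the given bound
intervals_clip <- function(ivs, lo = -Inf, hi = Inf) {
  out <- ivs[ivs$end >= lo & ivs$start <= hi, , drop = FALSE]
  if (nrow(out)) {
    out$start <- pmax(out$start, as.integer(max(lo, 1)))
    out$end <- pmin(out$end, as.integer(min(hi, .Machine$integer.max)))
  }
  rownames(out) <- NULL
  out
}

#' Construct a gene model
#'
#' Builds a stranded gene with exon/intron/CDS/UTR structure.  Introns are
#' the gaps between consecutive exons; UTRs are derived as the exonic
#' sequence outside the CDS (5' / 3' in transcript sense).
#'
#' @param gene_id gene identifier.
#' @param contig contig id.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive, genomic
#'   ascending; non-overlapping).
#' @param cds optional data.frame with `start`, `end` of coding intervals
#'   (must lie within exons).
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-' (%s)", gene_id)
  exons <- norm_intervals(exons)
  if (nrow(exons) == 0) stopf("gene '%s' has no exons", gene_id)
  cds <- norm_intervals(cds)
  g <- list(gene_id = gene_id, contig = contig, strand = strand,
            start = exons$start[1], end = exons$end[nrow(exons)],
            exons = exons, introns = gaps_between(exons), cds = cds,
            cds_ok = FALSE,
            utr5 = data.frame(start = integer(0), end = integer(0)),
            utr3 = data.frame(start = integer(0), end = integer(0)))
  if (nrow(cds) > 0) {
    cds_len <- intervals_len(cds)
    if (cds_len %% 3L != 0L) {
      warnf("gene '%s': CDS length %d not divisible by 3; excluded from effect annotation",
            gene_id, cds_len)
    } else {
      g$cds_ok <- TRUE
    }
    left <- intervals_clip(exons, hi = cds$start[1] - 1L)
    right <- intervals_clip(exons, lo = cds$end[nrow(cds)] + 1L)
    if (strand == "+") {
      g$utr5 <- left; g$utr3 <- right
    } else {
      g$utr5 <- right; g$utr3 <- left
    }
  }
  structure(g, class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s)  exons:%d introns:%d CDS:%s\n",
              x$gene_id, x$contig, x$start, x$end, x$strand,
              nrow(x$exons), nrow(x$introns),
              if (nrow(x$cds)) sprintf("%d bp", intervals_len(x$cds)) else "none"))
  invisible(x)
}

#' Load gene models from GFF3
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` features (1-based inclusive).  Exon and
#' CDS features are attached to genes via their `Parent` attribute,
#' resolving through an mRNA level when present.  Genes lacking CDS are
#' kept with an empty CDS; a CDS whose length is not divisible by 3
#' triggers a warning and excludes the gene from effect annotation only.
#'
#' @param gff_path path to a GFF3 file.
#' @return named list of [gene_model()] objects (names = gene ids).
#' @export
load_gene_models <- function(gff_path) {
  if (!file.exists(gff_path)) stopf("GFF file not found: %s", gff_path)
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))

  gene_rows <- which(df$type == "gene")
  if (!length(gene_rows)) stopf("no gene features in %s", gff_path)
  gene_ids <- ids[gene_rows]
  if (anyNA(gene_ids)) stopf("gene feature without ID attribute in %s", gff_path)

  ## map any transcript-level id to its gene
  tx_rows <- which(df$type %in% c("mRNA", "transcript"))
  to_gene <- setNames(gene_ids, gene_ids)
  to_gene <- c(to_gene, setNames(parents[tx_rows], ids[tx_rows]))

  res <- list()
  for (i in seq_along(gene_rows)) {
    gid <- gene_ids[i]
    owners <- names(to_gene)[to_gene == gid]
    child <- !is.na(parents) & parents %in% owners
    ex <- df[child & df$type == "exon", c("start", "end")]
    cd <- df[child & df$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0) {                    # exonless annotation: whole span
      ex <- df[gene_rows[i], c("start", "end")]
    }
    ex <- unique(ex); cd <- unique(cd)
    res[[gid]] <- gene_model(gid, df$seqnames[gene_rows[i]],
                             df$strand[gene_rows[i]], ex,
                             if (nrow(cd)) cd else NULL)
  }
  res
}

## ---- positional services --------------------------------------------------

in_intervals <- function(pos, ivs) {
  if (nrow(ivs) == 0) return(FALSE)
  any(pos >= ivs$start & pos <= ivs$end)
}

#' Classify a position within a gene
#'
#' @param gene a `GeneModel`.
#' @param pos genomic position (must lie in the gene span).
#' @return `"exon"` or `"intron"`.
#' @export
gene_feature <- function(gene, pos) {
  if (pos < gene$start || pos > gene$end) {
    stopf("position %d outside gene %s", pos, gene$gene_id)
  }
  if (in_intervals(pos, gene$exons)) "exon" else "intron"
}

#' Transcript-sense offset of a genomic position within the gene span
#'
#' 1-based: the gene's 5'-most base (in transcript sense) is 1.
#'
#' @inheritParams gene_feature
#' @export
transcript_position <- function(gene, pos) {
  if (gene$strand == "+") pos - gene$start + 1L else gene$end - pos + 1L
}

#' Unspliced or spliced gene sequence in transcript sense
#'
#' @param gene a `GeneModel`.
#' @param genome a `GenomeReference`.
#' @param spliced if `TRUE`, concatenate exons (the mature transcript);
#'   otherwise the full genomic span.
#' @return character scalar (reverse-complemented for `-` strand genes).
#' @export
gene_sequence <- function(gene, genome, spliced = FALSE) {
  s <- if (spliced) {
    paste(mapply(function(a, b) genome_seq(genome, gene$contig, a, b),
                 gene$exons$start, gene$exons$end),
          collapse = "")
  } else {
    genome_seq(genome, gene$contig, gene$start, gene$end)
  }
  if (gene$strand == "-") reverse_complement(s) else s
}

## spliced CDS coordinate (1-based, transcript sense) of a genomic position;
## NA if outside the CDS
cds_offset <- function(gene, pos) {
  cds <- gene$cds
  if (nrow(cds) == 0 || !in_intervals(pos, cds)) return(NA_integer_)
  lens <- cds$end - cds$start + 1L
  if (gene$strand == "+") {
    i <- which(pos >= cds$start & pos <= cds$end)
    sum(lens[seq_len(i - 1)]) + (pos - cds$start[i] + 1L)
  } else {
    i <- which(pos >= cds$start & pos <= cds$end)
    sum(lens[seq_len(nrow(cds)) > i]) + (cds$end[i] - pos + 1L)
  }
}

#' Assign genomic sites to genes
#'
#' Sites inside several genes are assigned to the gene with the smallest
#' span (ties broken by gene id) — the most specific model.
#'
#' @param contig,pos parallel vectors of site coordinates.
#' @param gene_models named list of `GeneModel`s.
#' @return character vector of gene ids, `NA` for intergenic sites.  The
#'   attribute `"ambiguous"` flags sites inside more than one gene.
#' @export
assign_gene <- function(contig, pos, gene_models) {
  if (!length(gene_models)) {
    return(structure(rep(NA_character_, length(pos)),
                     ambiguous = logical(length(pos))))
  }
  gtab <- data.frame(
    gene_id = vapply(gene_models, `[[`, character(1), "gene_id"),
    contig = vapply(gene_models, `[[`, character(1), "contig"),
    start = vapply(gene_models, `[[`, integer(1), "start"),
    end = vapply(gene_models, `[[`, integer(1), "end"),
    stringsAsFactors = FALSE)
  gtab$span <- gtab$end - gtab$start + 1L
  contig <- rep_len(contig, length(pos))
  out <- rep(NA_character_, length(pos))
  amb <- logical(length(pos))
  for (i in seq_along(pos)) {
    hit <- which(gtab$contig == contig[i] & gtab$start <= pos[i] & gtab$end >= pos[i])
    if (length(hit) == 0) next
    amb[i] <- length(hit) > 1
    hit <- hit[order(gtab$span[hit], gtab$gene_id[hit])]
    out[i] <- gtab$gene_id[hit[1]]
  }
  structure(out, ambiguous = amb)
}

#' Orient an edit into transcript sense
#'
#' Edits inside genes on the reverse (Crick) strand are reverse-
#' complemented so the edit type is reported in the sense of the
#' transcript; forward-strand and intergenic edits are left as-is.
#'
#' @param contig,pos site coordinates.
#' @param ref,alt genomic reference and alternative base.
#' @param gene_models named list of `GeneModel`s.
#' @param genome optional `GenomeReference`; when given, `ref` is checked
#'   against the genome base.
#' @return list of class `OrientedEdit`: genomic and transcript-sense
#'   bases, the edit-type label (e.g. `"C-to-T"`), and the hosting gene id
#'   or `"intergenic"`.
#' @export
orient_edit <- function(contig, pos, ref, alt, gene_models, genome = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is.null(genome)) {
    gb <- genome_base(genome, contig, pos)
    if (gb != ref) stopf("ref base '%s' disagrees with genome '%s' at %s:%d",
                         ref, gb, contig, pos)
  }
  gid_raw <- assign_gene(contig, pos, gene_models)
  gid <- as.character(gid_raw)[1]
  flip <- !is.na(gid) && gene_models[[gid]]$strand == "-"
  sref <- if (flip) complement_base(ref) else ref
  salt <- if (flip) complement_base(alt) else alt
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt,
                 sense_ref = sref, sense_alt = salt,
                 edit_type = paste0(sref, "-to-", salt),
                 gene_id = if (is.na(gid)) "intergenic" else gid,
                 ambiguous = attr(gid_raw, "ambiguous")[1]),
            class = "OrientedEdit")
}

#' Orient all edits in a site table
#'
#' Adds `gene_id`, `sense_ref`, `sense_alt` and `edit_type` columns to an
#' edit-site table.  Multi-allelic sites get the edit type `"multiple"`.
#'
#' @param sites an edit-site data.frame with `contig`, `pos`, `ref`, `alt`.
#' @param gene_models named list of `GeneModel`s.
#' @return `sites` with orientation columns added.
#' @export
orient_edits <- function(sites, gene_models) {
  gid <- assign_gene(sites$contig, sites$pos, gene_models)
  flip <- !is.na(gid) &
    vapply(gid, function(g) !is.na(g) && gene_models[[g]]$strand == "-", logical(1))
  sites$gene_id <- ifelse(is.na(gid), "intergenic", gid)
  multi <- grepl(",", sites$alt)
  sites$sense_ref <- ifelse(flip, complement_base(sites$ref), sites$ref)
  sites$sense_alt <- ifelse(flip,
                            vapply(strsplit(sites$alt, ","), function(a)
                              paste(complement_base(a), collapse = ","), character(1)),
                            sites$alt)
  sites$edit_type <- ifelse(multi, "multiple",
                            paste0(sites$sense_ref, "-to-", sites$sense_alt))
  sites
}
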