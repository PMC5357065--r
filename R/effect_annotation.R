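## SnpEff-style effect classification of genic edits against gene models,
## plus the per-class contingency analysis, the amino-acid change matrix
## and the non-synonymous vs synonymous delta-shift comparison.

EFFECT_CLASSES <- c("5' UTR", "Gain of start codon", "Loss of start codon",
                    "Synonymous coding", "Non-synonymous coding", "Intron",
                    "Gain of stop codon", "Loss of stop codon", "3' UTR")

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Classify the effect of one edit within a gene
#'
#' Intronic positions are `Intron`; exonic non-CDS positions are 5'/3'
#' UTR by transcript side; CDS positions are classified by translating
#' the affected codon with the standard genetic code.  Stop-codon gain or
#' loss takes precedence over (non-)synonymous; start gain/loss refers to
#' the annotated start codon only.
#'
#' @param gene a `GeneModel` hosting the position (error otherwise).
#' @param genome a `GenomeReference`.
#' @param pos genomic position of the edit.
#' @param ref,alt genomic reference and alternative base.
#' @return list of class `EffectAnnotation`: `gene_id`, `effect`, and for
#'   coding effects `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`,
#'   `protein_pos`.
#' @export
annotate_effect <- function(gene, genome, pos, ref, alt) {
  if (pos < gene$start || pos > gene$end) {
    stopf("position %d outside gene %s; assign sites to genes first",
          pos, gene$gene_id)
  }
  ref <- toupper(ref); alt <- toupper(alt)
  gb <- genome_base(genome, gene$contig, pos)
  if (gb != ref) stopf("ref base '%s' disagrees with genome '%s' at %s:%d",
                       ref, gb, gene$contig, pos)
  base <- list(gene_id = gene$gene_id, effect = NA_character_,
               codon_ref = NA_character_, codon_alt = NA_character_,
               aa_ref = NA_character_, aa_alt = NA_character_,
               protein_pos = NA_integer_)
  mk <- function(x) structure(x, class = "EffectAnnotation")

  if (!in_intervals(pos, gene$exons)) {
    base$effect <- "Intron"
    return(mk(base))
  }
  off <- cds_offset(gene, pos)
  if (is.na(off)) {
    if (nrow(gene$cds) == 0 || !gene$cds_ok) {
      stopf("gene %s has no usable CDS; cannot classify exonic effect",
            gene$gene_id)
    }
    ## exonic outside CDS: UTR side in transcript sense
    utr5_side <- if (gene$strand == "+") pos < gene$cds$start[1] else
      pos > gene$cds$end[nrow(gene$cds)]
    base$effect <- if (utr5_side) "5' UTR" else "3' UTR"
    return(mk(base))
  }
  if (!gene$cds_ok) {
    stopf("gene %s CDS length not divisible by 3; excluded from effect annotation",
          gene$gene_id)
  }
  cds_seq <- paste(mapply(function(a, b) genome_seq(genome, gene$contig, a, b),
                          gene$cds$start, gene$cds$end), collapse = "")
  if (gene$strand == "-") cds_seq <- reverse_complement(cds_seq)
  sref <- if (gene$strand == "-") complement_base(ref) else ref
  salt <- if (gene$strand == "-") complement_base(alt) else alt
  stopifnot(substr(cds_seq, off, off) == sref)
  codon_i <- (off - 1L) %/% 3L + 1L
  within <- (off - 1L) %% 3L + 1L
  codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  codon_alt <- codon
  substr(codon_alt, within, within) <- salt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(codon_alt)
  base$codon_ref <- codon; base$codon_alt <- codon_alt
  base$aa_ref <- aa_ref; base$aa_alt <- aa_alt
  base$protein_pos <- codon_i
  base$effect <-
    if (codon_i == 1L && codon_alt == "ATG" && codon != "ATG") "Gain of start codon"
    else if (codon_i == 1L && codon == "ATG" && codon_alt != "ATG") "Loss of start codon"
    else if (aa_alt == "*" && aa_ref != "*") "Gain of stop codon"
    else if (aa_ref == "*" && aa_alt != "*") "Loss of stop codon"
    else if (aa_ref == aa_alt) "Synonymous coding"
    else "Non-synonymous coding"
  mk(base)
}

#' @export
print.EffectAnnotation <- function(x, ...) {
  extra <- if (!is.na(x$aa_ref))
    sprintf(" (%s->%s, %s%d%s)", x$codon_ref, x$codon_alt, x$aa_ref,
            x$protein_pos, x$aa_alt) else ""
  cat(sprintf("EffectAnnotation: %s in %s%s\n", x$effect, x$gene_id, extra))
  invisible(x)
}

#' Annotate effects for a table of genic edits
#'
#' Multi-allelic sites contribute one annotation per alternative allele
#' (each editing event is a separate effect).  Sites in genes without a
#' usable CDS are skipped with a warning.
#'
#' @param sites edit-site table carrying `gene_id` (see [orient_edits()]);
#'   intergenic rows are ignored.
#' @param gene_models named list of `GeneModel`s.
#' @param genome a `GenomeReference`.
#' @return data.frame with one row per (edit, allele): `contig`, `pos`,
#'   `ref`, `alt`, `gene_id`, `effect`, codon/amino-acid columns.
#' @export
annotate_effects <- function(sites, gene_models, genome) {
  genic <- sites[!is.na(sites$gene_id) & sites$gene_id %in% names(gene_models), ,
                 drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(genic))) {
    g <- gene_models[[genic$gene_id[i]]]
    for (allele in strsplit(genic$alt[i], ",")[[1]]) {
      ann <- tryCatch(
        annotate_effect(g, genome, genic$pos[i], genic$ref[i], allele),
        error = function(e) NULL)
      if (is.null(ann)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        contig = genic$contig[i], pos = genic$pos[i], ref = genic$ref[i],
        alt = allele, gene_id = ann$gene_id, effect = ann$effect,
        codon_ref = ann$codon_ref, codon_alt = ann$codon_alt,
        aa_ref = ann$aa_ref, aa_alt = ann$aa_alt,
        protein_pos = ann$protein_pos)
    }
  }
  if (skipped) warnf("%d edit allele(s) skipped (unusable CDS)", skipped)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene_id = character(0), effect = character(0),
               codon_ref = character(0), codon_alt = character(0),
               aa_ref = character(0), aa_alt = character(0),
               protein_pos = integer(0))
  rownames(out) <- NULL
  out
}

#' Per-class enrichment of effects in a subset vs background
#'
#' For each of the nine effect classes, a two-sided Fisher's exact test
#' on the 2x2 table (class vs remainder, subset vs background), BH-
#' corrected across the nine classes.  The background may include the
#' subset (printed-table semantics).
#'
#' @param subset_counts,background_counts named integer vectors of
#'   per-class counts, or annotation data.frames from
#'   [annotate_effects()] (tallied via their `effect` column).
#' @return data.frame: `effect`, `subset_n`, `subset_pct`, `background_n`,
#'   `background_pct`, `p`, `q`.
#' @export
effect_contingency_tests <- function(subset_counts, background_counts) {
  tally <- function(x) {
    if (is.data.frame(x)) x <- table(factor(x$effect, levels = EFFECT_CLASSES))
    out <- setNames(rep(0L, length(EFFECT_CLASSES)), EFFECT_CLASSES)
    out[names(x)] <- as.integer(x)
    out
  }
  a <- tally(subset_counts)
  b <- tally(background_counts)
  na <- sum(a); nb <- sum(b)
  p <- vapply(EFFECT_CLASSES, function(cl) {
    if (a[cl] == 0 && b[cl] == 0) return(1)
    fisher.test(matrix(c(a[cl], na - a[cl], b[cl], nb - b[cl]), 2))$p.value
  }, numeric(1))
  data.frame(effect = EFFECT_CLASSES,
             subset_n = as.integer(a), subset_pct = 100 * a / na,
             background_n = as.integer(b), background_pct = 100 * b / nb,
             p = unname(p), q = bh_adjust(unname(p)),
             row.names = NULL)
}

#' Amino-acid change matrix for non-synonymous edits
#'
#' @param annotations data.frame from [annotate_effects()].
#' @return 20x20 integer matrix; rows = original amino acid, columns =
#'   post-editing amino acid; diagonal zero by construction.
#' @export
aa_change_matrix <- function(annotations) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(0L, 20, 20, dimnames = list(from = aas, to = aas))
  ns <- annotations[annotations$effect == "Non-synonymous coding", , drop = FALSE]
  ns <- ns[ns$aa_ref %in% aas & ns$aa_alt %in% aas, , drop = FALSE]
  if (nrow(ns)) {
    t <- table(factor(ns$aa_ref, levels = aas), factor(ns$aa_alt, levels = aas))
    m <- m + unclass(t)
  }
  storage.mode(m) <- "integer"
  m
}

#' Delta-shift comparison of non-synonymous vs synonymous edits
#'
#' The delta shift of an edit is the absolute difference of its mean edit
#' frequency between stressed and control replicates.  Groups (coding
#' edits with non-synonymous vs synonymous effects) are compared with a
#' two-tailed Welch t-test.
#'
#' @param freqs data.frame of per-replicate edit frequencies: columns
#'   `contig`, `pos`, `condition`, `freq` (one row per site x sample).
#' @param annotations data.frame from [annotate_effects()]; only
#'   `Synonymous coding` and `Non-synonymous coding` rows are used.
#' @param stress,control condition names.
#' @return list of class `DeltaShiftComparison`: `p.value`, group means,
#'   sizes, and the per-edit delta table.
#' @export
delta_shift_comparison <- function(freqs, annotations, stress,
                                   control = "control") {
  coding <- annotations[annotations$effect %in%
                          c("Synonymous coding", "Non-synonymous coding"), ,
                        drop = FALSE]
  key <- paste(coding$contig, coding$pos)
  fr <- freqs[freqs$condition %in% c(stress, control), , drop = FALSE]
  fr <- fr[paste(fr$contig, fr$pos) %in% key, , drop = FALSE]
  if (!nrow(fr)) stopf("no coding edits with frequency data")
  agg <- tapply(fr$freq, list(paste(fr$contig, fr$pos), fr$condition), mean)
  delta <- abs(agg[, stress] - agg[, control])
  cls <- coding$effect[match(names(delta), key)]
  ok <- !is.na(delta)
  delta <- delta[ok]; cls <- cls[ok]
  ns <- delta[cls == "Non-synonymous coding"]
  syn <- delta[cls == "Synonymous coding"]
  if (length(ns) < 2 || length(syn) < 2) {
    stopf("each group needs >= 2 edits (non-synonymous: %d, synonymous: %d)",
          length(ns), length(syn))
  }
  if (stats::sd(ns) == 0 && stats::sd(syn) == 0) {
    p <- if (isTRUE(all.equal(mean(ns), mean(syn)))) 1 else 0
  } else {
    p <- t.test(ns, syn, var.equal = FALSE)$p.value
  }
  structure(list(p.value = p, stress = stress,
                 mean_nonsyn = mean(ns), mean_syn = mean(syn),
                 n_nonsyn = length(ns), n_syn = length(syn),
                 deltas = data.frame(site = names(delta), class = cls,
                                     delta = unname(delta))),
            class = "DeltaShiftComparison")
}

#' @export
print.DeltaShiftComparison <- function(x, ...) {
  cat(sprintf(
    "Delta shift (%s vs control): non-syn %.3f (n=%d) vs syn %.3f (n=%d), Welch p = %.3g\n",
    x$stress, x$mean_nonsyn, x$n_nonsyn, x$mean_syn, x$n_syn, x$p.value))
  invisible(x)
}
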