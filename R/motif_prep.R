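## Sequence-context preparation for external motif discovery (MEME/MAST):
## per-edit-type window extraction in transcript sense, train/test split,
## and background windows from unedited genes.

#' Extract sequence contexts around edits, grouped by edit type
#'
#' For each genic edit, a window of `flank` bases either side of the edit
#' (201 bp by default) is extracted in transcript sense: in `"genic"`
#' context from the unspliced gene sequence (co-transcriptional editing),
#' in `"exonic"` context from the spliced transcript (post-transcriptional
#' editing).  Windows truncated at feature boundaries are emitted at
#' reduced length with a flag.  Edits outside genes (or outside exons in
#' exonic mode) are skipped with a warning.
#'
#' @param sites edit-site table carrying `gene_id` and `edit_type` (see
#'   [orient_edits()]).
#' @param genome a `GenomeReference`.
#' @param gene_models named list of `GeneModel`s.
#' @param flank bases either side of the edit (default 100).
#' @param context `"genic"` or `"exonic"`.
#' @return named list (one element per edit type) of data.frames with
#'   `name`, `seq`, `truncated`, `n_edits` (edited positions inside the
#'   window, including the focal edit).
#' @export
extract_windows <- function(sites, genome, gene_models, flank = 100,
                            context = c("genic", "exonic")) {
  context <- match.arg(context)
  skipped <- 0L
  rows <- list()
  ## per-gene transcript-sense coordinates of all edits, for n_edits
  genic <- sites[sites$gene_id %in% names(gene_models), , drop = FALSE]
  for (i in seq_len(nrow(genic))) {
    g <- gene_models[[genic$gene_id[i]]]
    if (context == "genic") {
      seq_len_g <- g$end - g$start + 1L
      off <- transcript_position(g, genic$pos[i])
      all_offs <- transcript_position(g, genic$pos[genic$gene_id == g$gene_id])
      gseq <- gene_sequence(g, genome, spliced = FALSE)
    } else {
      offs_tab <- exonic_offset(g, genic$pos[genic$gene_id == g$gene_id])
      off <- exonic_offset(g, genic$pos[i])
      if (is.na(off)) { skipped <- skipped + 1L; next }
      all_offs <- offs_tab[!is.na(offs_tab)]
      gseq <- gene_sequence(g, genome, spliced = TRUE)
      seq_len_g <- nchar(gseq)
    }
    a <- max(1L, off - flank)
    b <- min(seq_len_g, off + flank)
    rows[[length(rows) + 1]] <- data.frame(
      edit_type = genic$edit_type[i],
      name = sprintf("%s|%s:%d|%s|%s", g$gene_id, genic$contig[i],
                     genic$pos[i], genic$edit_type[i], context),
      seq = substr(gseq, a, b),
      truncated = (b - a + 1L) < (2L * flank + 1L),
      n_edits = sum(all_offs >= a & all_offs <= b))
  }
  n_intergenic <- nrow(sites) - nrow(genic)
  if (n_intergenic + skipped > 0) {
    warnf("%d edit(s) outside usable %s context skipped",
          n_intergenic + skipped, context)
  }
  if (!length(rows)) return(list())
  all <- do.call(rbind, rows)
  lapply(split(all[-1], all$edit_type), function(d) {
    rownames(d) <- NULL
    d
  })
}

## spliced-transcript coordinate of genomic positions (NA if intronic)
exonic_offset <- function(gene, pos) {
  ex <- gene$exons
  lens <- ex$end - ex$start + 1L
  out <- vapply(pos, function(p) {
    j <- which(p >= ex$start & p <= ex$end)
    if (!length(j)) return(NA_integer_)
    if (gene$strand == "+") {
      sum(lens[seq_len(j - 1L)]) + (p - ex$start[j] + 1L)
    } else {
      sum(lens[seq_len(nrow(ex)) > j]) + (ex$end[j] - p + 1L)
    }
  }, integer(1))
  out
}

#' Split windows into training and test sets
#'
#' Half of the windows are chosen at random as the training set; windows
#' containing more than one edited position are then moved to the test
#' set so the training signal stays clean.
#'
#' @param windows data.frame from one element of [extract_windows()].
#' @param seed RNG seed (same seed, same split).
#' @return list with `train` and `test` data.frames (disjoint; their
#'   union is the input).
#' @export
split_train_test <- function(windows, seed = 1) {
  n <- nrow(windows)
  if (n < 2) {
    warnf("fewer than 2 windows; all assigned to training set")
    return(list(train = windows, test = windows[0, , drop = FALSE]))
  }
  set.seed(seed)
  idx <- sample.int(n, n %/% 2)
  train <- windows[idx, , drop = FALSE]
  test <- windows[-idx, , drop = FALSE]
  multi <- train$n_edits > 1
  test <- rbind(test, train[multi, , drop = FALSE])
  train <- train[!multi, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Background windows from unedited genes
#'
#' Samples fixed-width windows uniformly from genes carrying no edits —
#' the false-negative evaluation set for motif scanning.
#'
#' @param genome a `GenomeReference`.
#' @param gene_models named list of `GeneModel`s.
#' @param sites edit-site table (genes appearing here are excluded).
#' @param n number of windows (default 10000).
#' @param width window width (default 201).
#' @param seed RNG seed.
#' @return data.frame with `name` and `seq`.
#' @export
sample_background_windows <- function(genome, gene_models, sites, n = 10000,
                                      width = 201, seed = 1) {
  edited <- unique(sites$gene_id)
  pool <- gene_models[!names(gene_models) %in% edited]
  pool <- pool[vapply(pool, function(g) g$end - g$start + 1L >= width, logical(1))]
  if (!length(pool)) stopf("no unedited gene long enough for %d-bp windows", width)
  set.seed(seed)
  gi <- sample.int(length(pool), n, replace = TRUE)
  out <- data.frame(name = character(n), seq = character(n))
  for (i in seq_len(n)) {
    g <- pool[[gi[i]]]
    gseq <- gene_sequence(g, genome, spliced = FALSE)
    a <- sample.int(nchar(gseq) - width + 1L, 1)
    out$name[i] <- sprintf("%s|bg%d", g$gene_id, i)
    out$seq[i] <- substr(gseq, a, a + width - 1L)
  }
  out
}

#' Write windows as FASTA
#'
#' @param windows data.frame with `name` and `seq` columns.
#' @param path output FASTA path.
#' @export
write_windows_fasta <- function(windows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(windows))) {
    writeLines(c(paste0(">", windows$name[i]), windows$seq[i]), con)
  }
  invisible(path)
}
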