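## Per-gene binomial GLM test of condition-specific differential editing:
## cbind(edited, unedited) ~ condition * position (logit link), tested by
## analysis of deviance against the position-only model.  Replicates enter
## as individual rows (never pooled) so each replicate carries equal
## weight.

#' Build per-gene edit profiles
#'
#' Collects, for every genic edit site and every sample, the number of
#' edited (alt-allele) and unedited reads at that position.  Positions
#' with zero coverage in a sample are recorded as missing (the row is
#' absent), not as zero.
#'
#' @param sites filtered edit-site table carrying `gene_id` (see
#'   [orient_edits()]); intergenic sites contribute nothing.
#' @param sample_counts named list of per-sample `SiteCountTable`s.
#' @param sample_info data.frame with columns `sample_id` (matching
#'   `names(sample_counts)`), `condition`, `replicate`.
#' @return data.frame of class `GeneEditProfile` with columns `gene_id`,
#'   `contig`, `pos`, `sample_id`, `condition`, `replicate`, `edited`,
#'   `unedited`.
#' @export
build_gene_profiles <- function(sites, sample_counts, sample_info) {
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(sample_info)))
  miss <- setdiff(sample_info$sample_id, names(sample_counts))
  if (length(miss)) stopf("sample_counts missing sample '%s'", miss[1])
  genic <- sites[!is.na(sites$gene_id) & sites$gene_id != "intergenic", ,
                 drop = FALSE]
  rows <- list()
  for (si in seq_len(nrow(sample_info))) {
    sid <- sample_info$sample_id[si]
    tab <- sample_counts[[sid]]
    key <- paste(tab$contig, tab$pos)
    idx <- match(paste(genic$contig, genic$pos), key)
    hit <- which(!is.na(idx))
    if (!length(hit)) next
    bt <- base_totals(tab)
    colnames(bt) <- BASES
    cov <- site_coverage(tab)[idx[hit]]
    edited <- vapply(seq_along(hit), function(j) {
      alleles <- strsplit(genic$alt[hit[j]], ",")[[1]]
      sum(bt[idx[hit[j]], alleles])
    }, numeric(1))
    keep <- cov > 0
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = genic$gene_id[hit[keep]], contig = genic$contig[hit[keep]],
      pos = genic$pos[hit[keep]], sample_id = sid,
      condition = sample_info$condition[si],
      replicate = sample_info$replicate[si],
      edited = as.integer(edited[keep]),
      unedited = as.integer(cov[keep] - edited[keep]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), contig = character(0), pos = integer(0),
               sample_id = character(0), condition = character(0),
               replicate = character(0), edited = integer(0),
               unedited = integer(0))
  rownames(out) <- NULL
  class(out) <- c("GeneEditProfile", "data.frame")
  out
}

#' Filter genes testable for a contrast
#'
#' Keeps genes with at least `min_positions` edited positions covered by
#' at least `min_coverage` reads in every replicate of both conditions of
#' the contrast.
#'
#' @param profiles a `GeneEditProfile` data.frame.
#' @param contrast character vector `c(stress, control)`.
#' @param min_positions minimum qualifying positions (default 2).
#' @param min_coverage minimum reads per replicate at a qualifying
#'   position (default 1).
#' @return the profiles restricted to testable genes (and to the two
#'   contrast conditions).
#' @export
filter_testable_genes <- function(profiles, contrast, min_positions = 2,
                                  min_coverage = 1) {
  pr <- profiles[profiles$condition %in% contrast, , drop = FALSE]
  reps <- unique(pr[c("condition", "replicate")])
  n_rep <- nrow(reps)
  keep_genes <- vapply(split(pr, pr$gene_id), function(g) {
    g <- g[g$edited + g$unedited >= min_coverage, , drop = FALSE]
    per_pos <- tapply(paste(g$condition, g$replicate), g$pos,
                      function(x) length(unique(x)))
    sum(per_pos == n_rep) >= min_positions
  }, logical(1))
  out <- pr[pr$gene_id %in% names(keep_genes)[keep_genes], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GeneEditProfile", "data.frame")
  out
}

#' Fit the per-gene differential-editing GLM
#'
#' Full model: `cbind(edited, unedited) ~ condition * position`
#' (binomial, logit link); reduced model: `~ position`.  The test
#' statistic is the deviance difference, referred to a chi-squared
#' distribution with df equal to the difference in parameter count
#' (condition main effect plus condition-by-position interaction).
#'
#' @param gene_profile rows of a `GeneEditProfile` for one gene, already
#'   restricted to the two contrast conditions.
#' @param contrast character vector `c(stress, control)`; the control
#'   level is the baseline.
#' @return list: `gene_id`, `statistic`, `df`, `p.value`, `converged`,
#'   `shift` (per-position mean frequency difference stress - control).
#' @export
fit_differential_glm <- function(gene_profile, contrast) {
  d <- gene_profile[gene_profile$condition %in% contrast, , drop = FALSE]
  d$condition <- factor(d$condition, levels = c(contrast[2], contrast[1]))
  d$position <- factor(d$pos)
  ctl <- glm.control(epsilon = 1e-8, maxit = 25)
  fit_ok <- TRUE
  full <- tryCatch(
    suppressWarnings(glm(cbind(edited, unedited) ~ condition * position,
                         family = binomial(), data = d, control = ctl)),
    error = function(e) NULL)
  reduced <- tryCatch(
    suppressWarnings(glm(cbind(edited, unedited) ~ position,
                         family = binomial(), data = d, control = ctl)),
    error = function(e) NULL)
  if (is.null(full) || is.null(reduced) || !full$converged || !reduced$converged) {
    fit_ok <- FALSE
  }
  freq <- d$edited / (d$edited + d$unedited)
  mf <- tapply(freq, list(d$position, d$condition), mean)
  shift <- mf[, contrast[1]] - mf[, contrast[2]]
  if (!fit_ok) {
    return(list(gene_id = d$gene_id[1], statistic = NA_real_, df = NA_integer_,
                p.value = NA_real_, converged = FALSE, shift = shift))
  }
  stat <- max(0, reduced$deviance - full$deviance)
  df <- reduced$df.residual - full$df.residual
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(gene_id = d$gene_id[1], statistic = stat, df = as.integer(df),
       p.value = p, converged = TRUE, shift = shift)
}

#' Differential-editing analysis across contrasts
#'
#' For each stressor-vs-control contrast: apply the testability filter,
#' fit the per-gene GLM, and BH-correct p-values across all genes tested
#' for that contrast (non-converged fits are excluded from the family).
#' Genes with corrected p below `alpha` are called differentially edited.
#'
#' @param profiles a `GeneEditProfile` data.frame.
#' @param stress_conditions character vector of stressor names.
#' @param control name of the control condition (default `"control"`).
#' @param alpha significance threshold on the corrected p (default 0.05).
#' @param min_positions,min_coverage passed to [filter_testable_genes()].
#' @return object of class `DifferentialEditingResult`: `results` (named
#'   list of per-contrast data.frames with `gene_id`, `statistic`, `df`,
#'   `p`, `q`, `significant`), `summary` (per-contrast significant
#'   counts, union count, overlap matrix), `alpha`.
#' @export
differential_editing <- function(profiles, stress_conditions,
                                 control = "control", alpha = 0.05,
                                 min_positions = 2, min_coverage = 1) {
  results <- list()
  sig_genes <- list()
  for (stress in stress_conditions) {
    contrast <- c(stress, control)
    pr <- filter_testable_genes(profiles, contrast, min_positions, min_coverage)
    genes <- unique(pr$gene_id)
    if (!length(genes)) {
      results[[stress]] <- data.frame(gene_id = character(0),
                                      statistic = numeric(0), df = integer(0),
                                      p = numeric(0), q = numeric(0),
                                      significant = logical(0))
      sig_genes[[stress]] <- character(0)
      next
    }
    fits <- lapply(genes, function(g)
      fit_differential_glm(pr[pr$gene_id == g, , drop = FALSE], contrast))
    res <- data.frame(
      gene_id = vapply(fits, `[[`, character(1), "gene_id"),
      statistic = vapply(fits, `[[`, numeric(1), "statistic"),
      df = vapply(fits, function(f) as.integer(f$df %||% NA), integer(1)),
      p = vapply(fits, `[[`, numeric(1), "p.value"))
    ok <- !is.na(res$p)
    res$q <- NA_real_
    res$q[ok] <- bh_adjust(res$p[ok])
    res$significant <- !is.na(res$q) & res$q < alpha
    res <- res[order(res$p), , drop = FALSE]
    rownames(res) <- NULL
    results[[stress]] <- res
    sig_genes[[stress]] <- res$gene_id[res$significant]
  }
  union_genes <- unique(unlist(sig_genes))
  overlap <- outer(stress_conditions, stress_conditions,
                   Vectorize(function(a, b)
                     length(intersect(sig_genes[[a]], sig_genes[[b]]))))
  dimnames(overlap) <- list(stress_conditions, stress_conditions)
  multi <- if (length(sig_genes)) {
    tab <- table(unlist(sig_genes))
    sum(tab >= 2)
  } else 0L
  structure(list(results = results,
                 summary = list(
                   per_contrast = vapply(sig_genes, length, integer(1)),
                   tested = vapply(results, nrow, integer(1)),
                   union = length(union_genes),
                   union_genes = union_genes,
                   multi_stressor = multi,
                   overlap = overlap),
                 alpha = alpha),
            class = "DifferentialEditingResult")
}

#' @export
print.DifferentialEditingResult <- function(x, ...) {
  cat(sprintf("Differential editing (q < %g):\n", x$alpha))
  for (s in names(x$results)) {
    cat(sprintf("  %s: %d of %d tested genes significant\n",
                s, x$summary$per_contrast[[s]], x$summary$tested[[s]]))
  }
  cat(sprintf("  union: %d gene(s); %d responding to multiple stressors\n",
              x$summary$union, x$summary$multi_stressor))
  invisible(x)
}

#' Export differential-editing results
#'
#' Writes one TSV per contrast plus a JSON summary.
#'
#' @param x a `DifferentialEditingResult`.
#' @param dir output directory.
#' @export
write_differential_results <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(x$results)) {
    write.table(x$results[[s]], file.path(dir, paste0("diffedit_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sm <- x$summary
  jsonlite::write_json(
    list(per_contrast = as.list(sm$per_contrast), tested = as.list(sm$tested),
         union = sm$union, multi_stressor = sm$multi_stressor,
         overlap = sm$overlap, alpha = x$alpha),
    file.path(dir, "diffedit_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
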