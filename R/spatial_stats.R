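## Positional distribution of genic edits and the Monte-Carlo
## neighbour-distance clustering test.

#' Relative positions of edits along genes, exons or introns
#'
#' Positions are expressed in transcript sense (5' -> 3' of the gene's
#' strand) and normalised to \[0, 1\]:
#' `(offset within the feature) / (feature length - 1)`; a length-1
#' feature places its edit at 0.
#'
#' @param sites edit-site table carrying `gene_id` (see [orient_edits()]).
#' @param gene_models named list of `GeneModel`s.
#' @param feature `"gene"` (full span), `"exon"` or `"intron"` (position
#'   within the containing exon/intron; edits outside that feature class
#'   are dropped).
#' @param bin_width histogram bin width in relative distance
#'   (default 0.025).
#' @return object of class `PositionalHistogram`: `relpos`, `counts`,
#'   `breaks`, `feature`, `bin_width`.
#' @export
relative_positions <- function(sites, gene_models,
                               feature = c("gene", "exon", "intron"),
                               bin_width = 0.025) {
  feature <- match.arg(feature)
  genic <- sites[sites$gene_id %in% names(gene_models), , drop = FALSE]
  rel <- numeric(0)
  for (i in seq_len(nrow(genic))) {
    g <- gene_models[[genic$gene_id[i]]]
    pos <- genic$pos[i]
    if (feature == "gene") {
      len <- g$end - g$start + 1L
      off <- transcript_position(g, pos)
    } else {
      ivs <- if (feature == "exon") g$exons else g$introns
      j <- which(pos >= ivs$start & pos <= ivs$end)
      if (!length(j)) next
      len <- ivs$end[j] - ivs$start[j] + 1L
      off <- if (g$strand == "+") pos - ivs$start[j] + 1L else ivs$end[j] - pos + 1L
    }
    rel <- c(rel, if (len == 1L) 0 else (off - 1) / (len - 1))
  }
  nb <- as.integer(round(1 / bin_width))
  bin <- pmin(floor(rel / bin_width) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  structure(list(relpos = rel, counts = counts,
                 breaks = seq(0, 1, length.out = nb + 1L),
                 feature = feature, bin_width = bin_width),
            class = "PositionalHistogram")
}

#' @export
print.PositionalHistogram <- function(x, ...) {
  cat(sprintf("PositionalHistogram (%s): %d edits in %d bins of width %g\n",
              x$feature, length(x$relpos), length(x$counts), x$bin_width))
  invisible(x)
}

#' Binomial test for 5'-end enrichment of edits
#'
#' One-sided upper-tail binomial test of the number of edits with
#' relative position below `cutoff` against a uniform null proportion of
#' `cutoff`.
#'
#' @param x a `PositionalHistogram` or a numeric vector of relative
#'   positions.
#' @param cutoff the "initial" fraction of the gene tested (default 0.05).
#' @return the p-value; attributes `k` and `n` carry the counts.
#' @export
five_prime_enrichment_test <- function(x, cutoff = 0.05) {
  rel <- if (inherits(x, "PositionalHistogram")) x$relpos else x
  n <- length(rel)
  if (n == 0) stopf("no edits to test for 5' enrichment")
  k <- sum(rel < cutoff)
  p <- binom.test(k, n, p = cutoff, alternative = "greater")$p.value
  structure(p, k = k, n = n)
}

#' Group edit positions by gene
#'
#' @param sites edit-site table carrying `gene_id`.
#' @param gene_models named list of `GeneModel`s.
#' @return named list of sorted genomic positions, one element per edited
#'   gene.
#' @export
edits_by_gene <- function(sites, gene_models) {
  genic <- sites[sites$gene_id %in% names(gene_models), , drop = FALSE]
  lapply(split(genic$pos, genic$gene_id), function(p) sort(unique(p)))
}

#' Neighbour distances of edits within genes
#'
#' For every gene with at least two edits, each edit contributes the mean
#' of the distances to its upstream and downstream neighbours; terminal
#' edits contribute their single flanking distance.  Genes with fewer
#' than two edits contribute nothing.
#'
#' @param positions_by_gene named list of sorted position vectors.
#' @return numeric vector of distances (one per contributing edit).
#' @export
neighbor_distances <- function(positions_by_gene) {
  out <- lapply(positions_by_gene, function(p) {
    p <- sort(p)
    k <- length(p)
    if (k < 2) return(numeric(0))
    gaps <- diff(p)
    if (k == 2) return(c(gaps, gaps))
    c(gaps[1], (gaps[-(k - 1)] + gaps[-1]) / 2, gaps[k - 1])
  })
  unlist(out, use.names = FALSE)
}

## distances for one gene's shuffled placements: positions matrix k x B
## (columns sorted); returns k x B distance matrix
shuffle_distances <- function(pmat) {
  k <- nrow(pmat)
  gaps <- pmat[-1, , drop = FALSE] - pmat[-k, , drop = FALSE]
  if (k == 2) return(rbind(gaps, gaps))
  rbind(gaps[1, ],
        (gaps[-(k - 1), , drop = FALSE] + gaps[-1, , drop = FALSE]) / 2,
        gaps[k - 1, ])
}

## merge adjacent bins left-to-right until every group's expected >= min_e
pool_bins <- function(obs, exp, min_e = 5) {
  go <- numeric(0); ge <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(exp)) {
    co <- co + obs[i]; ce <- ce + exp[i]
    if (ce >= min_e) {
      go <- c(go, co); ge <- c(ge, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0 || co > 0) {               # tail short of min_e: fold back
    if (length(ge)) {
      go[length(go)] <- go[length(go)] + co
      ge[length(ge)] <- ge[length(ge)] + ce
    } else {
      go <- co; ge <- ce
    }
  }
  list(obs = go, exp = ge)
}

#' Monte-Carlo clustering test for edit positions
#'
#' Tests whether edits sit closer to their neighbours than expected by
#' chance.  Per shuffle, each gene's edits are re-placed uniformly at
#' random (without replacement) over the gene's positions, preserving the
#' per-gene edit count; the expected neighbour-distance distribution is
#' the mean histogram over shuffles.  Observed and expected counts are
#' compared with a chi-squared statistic over unit-distance bins up to
#' the 99th percentile of the pooled distances (remainder pooled), with
#' adjacent bins merged until every expected count reaches
#' `min_expected`; df = bins - 1.
#'
#' @param positions_by_gene named list of sorted edit positions.
#' @param gene_lengths named vector of gene span lengths (bases), covering
#'   at least the genes in `positions_by_gene`.
#' @param n_shuffles number of Monte-Carlo shuffles (default 10000).
#' @param seed RNG seed (recorded in the result).
#' @param max_quantile pooled-distance quantile capping the unit bins
#'   (default 0.99).
#' @param min_expected minimum expected count per chi-squared bin
#'   (default 5).
#' @return object of class `ClusteringTestResult`.
#' @export
clustering_test <- function(positions_by_gene, gene_lengths,
                            n_shuffles = 10000, seed = 1,
                            max_quantile = 0.99, min_expected = 5) {
  pbg <- positions_by_gene[lengths(positions_by_gene) >= 2]
  if (!length(pbg)) stopf("no gene with >= 2 edits; clustering test undefined")
  miss <- setdiff(names(pbg), names(gene_lengths))
  if (length(miss)) stopf("gene_lengths missing for: %s", miss[1])
  obs <- neighbor_distances(pbg)

  set.seed(seed)
  B <- as.integer(n_shuffles)
  shuf <- vector("list", length(pbg))
  for (gi in seq_along(pbg)) {
    k <- length(pbg[[gi]])
    L <- as.integer(gene_lengths[[names(pbg)[gi]]])
    if (L < k) stopf("gene %s shorter than its edit count", names(pbg)[gi])
    pmat <- vapply(seq_len(B), function(b) sort.int(sample.int(L, k)),
                   integer(k))
    stopifnot(nrow(pmat) == k)          # per-gene edit count conserved
    shuf[[gi]] <- shuffle_distances(pmat)
  }
  shuf_all <- unlist(shuf, use.names = FALSE)

  cap <- max(1, ceiling(quantile(c(shuf_all, obs), max_quantile, names = FALSE)))
  bin_of <- function(d) pmin(pmax(ceiling(d), 1), cap + 1)
  exp_counts <- tabulate(bin_of(shuf_all), nbins = cap + 1) / B
  obs_counts <- tabulate(bin_of(obs), nbins = cap + 1)
  pooled <- pool_bins(obs_counts, exp_counts, min_expected)
  stat <- sum((pooled$obs - pooled$exp)^2 / pooled$exp)
  df <- length(pooled$exp) - 1L
  p <- if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(list(observed = obs_counts, expected = exp_counts,
                 observed_pooled = pooled$obs, expected_pooled = pooled$exp,
                 distances = obs, statistic = stat, df = df, p.value = p,
                 n_shuffles = B, seed = seed,
                 binning = sprintf(
                   "unit bins to %d (q%.2f of pooled distances), overflow pooled, expected >= %g per bin",
                   cap, max_quantile, min_expected)),
            class = "ClusteringTestResult")
}

#' @export
print.ClusteringTestResult <- function(x, ...) {
  cat(sprintf(
    "Clustering test: X-squared = %.3f, df = %d, p = %.3g\n(%d shuffles, seed %d; %s)\n",
    x$statistic, x$df, x$p.value, x$n_shuffles, x$seed, x$binning))
  invisible(x)
}

#' Export a clustering-test result
#'
#' Writes `<prefix>_distances.tsv` (observed and expected bin counts) and
#' `<prefix>_meta.json` (statistic, df, p, shuffles, seed, binning).
#'
#' @param x a `ClusteringTestResult`.
#' @param prefix output path prefix.
#' @export
write_clustering_result <- function(x, prefix) {
  tab <- data.frame(distance_bin = seq_along(x$observed),
                    observed = x$observed, expected = x$expected)
  write.table(tab, paste0(prefix, "_distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(statistic = x$statistic, df = x$df, p_value = x$p.value,
               n_shuffles = x$n_shuffles, seed = x$seed, binning = x$binning)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
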