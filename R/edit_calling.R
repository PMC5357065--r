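## Significance calling of edited sites under a binomial sequencing-error
## model: at a site with coverage n, the number of miscalled reads is
## B(n, p) with p = 0.01 (Phred 20, the maximum plausible error rate).

#' Edit-calling configuration
#'
#' @param error_rate per-read miscall probability p of the binomial error
#'   model (default 0.01, i.e. Phred 20).
#' @param sig_threshold call threshold on the BH-corrected p-value
#'   (default 0.01).
#' @param multi_freq overall edit-frequency floor for reporting a site as
#'   edited to multiple bases (default 0.20).
#' @param multi_min_reads minimum reads supporting each alternative allele
#'   of a multi-edit site (default 2).
#' @param family multiple-testing family: `"candidates"` (all sites with
#'   at least one non-reference read; default) or `"covered"` (all covered
#'   positions).
#' @return list of class `EditCallConfig`.
#' @export
edit_call_config <- function(error_rate = 0.01, sig_threshold = 0.01,
                             multi_freq = 0.20, multi_min_reads = 2,
                             family = c("candidates", "covered")) {
  stopifnot(error_rate > 0, error_rate < 1,
            sig_threshold > 0, sig_threshold < 1,
            multi_freq > 0, multi_freq < 1, multi_min_reads >= 1)
  structure(list(error_rate = error_rate, sig_threshold = sig_threshold,
                 multi_freq = multi_freq, multi_min_reads = multi_min_reads,
                 family = match.arg(family)),
            class = "EditCallConfig")
}

#' Upper-tail binomial p-value for an edited site
#'
#' P(X >= k) for X ~ Binomial(n, p): the probability of observing at
#' least `k` miscalled reads among `n` under pure sequencing error.
#'
#' @param k edited (non-reference) read count, vectorised.
#' @param n total coverage, vectorised.
#' @param p error rate (default 0.01).
#' @return numeric vector of upper-tail probabilities.
#' @export
edit_pvalue <- function(k, n, p = 0.01) {
  if (any(n < 1)) stopf("coverage n must be >= 1")
  if (any(k < 0) || any(k > n)) stopf("k must satisfy 0 <= k <= n")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH q-values, capped at 1.  `m` can be set larger than
#' `length(p)` to adjust within a wider family (e.g. all covered
#' positions when only candidates carry p-values).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m family size (default `length(p)`).
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  n <- length(p)
  if (m < n) stopf("family size m cannot be smaller than length(p)")
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / seq(n, 1) * p[o]))[ro]
  q
}

#' Call significantly edited sites from pooled counts
#'
#' Candidate sites are covered positions with at least one non-reference
#' read.  The test statistic aggregates all non-reference reads
#' (`k_any`); allele assignment happens after significance: a site is
#' reported as edited to multiple bases when at least two alternative
#' alleles each have `multi_min_reads` supporting reads and the overall
#' frequency reaches `multi_freq`; otherwise only the majority allele is
#' reported and minority-allele reads stay in `n` but not in `k`.
#'
#' @param counts pooled `SiteCountTable` (all samples merged).
#' @param config an [edit_call_config()].
#' @return data.frame of class `EditSiteTable`, one row per candidate
#'   site, ordered by (contig, position): columns `contig`, `pos`, `ref`,
#'   `alt` (comma-separated when multiple), `n`, `k`, `f`, `k_any`,
#'   `pval`, `qval`, `significant`, `multi_allelic`, `edit_fwd`,
#'   `edit_rev` (NA when the input is unstranded).
#' @export
call_edits <- function(counts, config = edit_call_config()) {
  stranded <- isTRUE(attr(counts, "stranded"))
  n <- site_coverage(counts)
  bt <- base_totals(counts)           # columns A C G T, both strands
  colnames(bt) <- BASES
  ref_idx <- match(counts$ref, BASES)
  ref_n <- bt[cbind(seq_len(nrow(bt)), ref_idx)]
  k_any <- n - ref_n
  cand <- which(n >= 1 & k_any >= 1)
  if (!length(cand)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n = integer(0), k = integer(0), f = numeric(0),
                      k_any = integer(0), pval = numeric(0),
                      qval = numeric(0), significant = logical(0),
                      multi_allelic = logical(0),
                      edit_fwd = integer(0), edit_rev = integer(0))
    class(out) <- c("EditSiteTable", "data.frame")
    return(out)
  }
  m_family <- if (config$family == "covered") sum(n >= 1) else length(cand)
  pv <- edit_pvalue(k_any[cand], n[cand], config$error_rate)
  qv <- bh_adjust(pv, m = m_family)

  cm <- as.matrix(counts[COUNT_COLS])
  alt <- character(length(cand)); k <- integer(length(cand))
  multi <- logical(length(cand))
  efwd <- rep(NA_integer_, length(cand)); erev <- rep(NA_integer_, length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    ac <- bt[i, -ref_idx[i]]                       # alt allele counts
    ac <- sort(ac[ac > 0], decreasing = TRUE)
    qualify <- ac[ac >= config$multi_min_reads]
    overall_f <- k_any[i] / n[i]
    if (length(qualify) >= 2 && overall_f >= config$multi_freq) {
      multi[j] <- TRUE
      alleles <- names(qualify)
      k[j] <- sum(qualify)
    } else {
      alleles <- names(ac)[1]                      # majority allele
      k[j] <- ac[[1]]
    }
    alt[j] <- paste(alleles, collapse = ",")
    if (stranded) {
      efwd[j] <- sum(cm[i, paste0(alleles, "_fwd")])
      erev[j] <- sum(cm[i, paste0(alleles, "_rev")])
    }
  }
  out <- data.frame(contig = counts$contig[cand], pos = counts$pos[cand],
                    ref = counts$ref[cand], alt = alt, n = n[cand], k = k,
                    f = k / n[cand], k_any = k_any[cand], pval = pv,
                    qval = qv, significant = qv < config$sig_threshold,
                    multi_allelic = multi, edit_fwd = efwd, edit_rev = erev)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EditSiteTable", "data.frame")
  out
}

#' Write an edit-site table as TSV
#'
#' @param sites an `EditSiteTable`.
#' @param path output path.
#' @export
write_edit_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edit-site table written by [write_edit_sites()]
#'
#' @param path TSV path.
#' @return an `EditSiteTable`.
#' @export
read_edit_sites <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("EditSiteTable", "data.frame")
  out
}
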