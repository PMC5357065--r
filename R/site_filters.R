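## The five post-calling artefact filters.  Each is a pure predicate on a
## called site; apply_filters() records a flag per filter and an audit of
## survivors after each cascade stage.

#' Filter configuration
#'
#' @param min_freq,max_freq inclusive edit-frequency bounds (defaults 0.05
#'   and 0.95): below-5% sites are of little interest, above-95% sites
#'   guard against mis-sequenced reference bases.
#' @param flank bases either side of a site for the uniqueness window
#'   (default 100, i.e. a 201-bp window).
#' @param evalue_cutoff e-value at or below which a non-self match fails
#'   the uniqueness filter (default 1e-5).
#' @param strand_bias_threshold fraction of edit-supporting reads on one
#'   strand above which (strictly) a site fails (default 0.85).
#' @param intron_margin bases at each intron end within which a site fails
#'   (default 9).
#' @param dna_mode `"strict"` (sites without clean DNA support fail) or
#'   `"flagged"` (zero-DNA-coverage sites pass with a flag).
#' @param seed_length exact-match seed length for the internal uniqueness
#'   search (default 16).
#' @param bias_scope strand bias computed over `"edit"`-supporting reads
#'   (default) or `"all"` covering reads.
#' @return list of class `FilterConfig`.
#' @export
filter_config <- function(min_freq = 0.05, max_freq = 0.95, flank = 100,
                          evalue_cutoff = 1e-5, strand_bias_threshold = 0.85,
                          intron_margin = 9,
                          dna_mode = c("strict", "flagged"),
                          seed_length = 16, bias_scope = c("edit", "all")) {
  stopifnot(min_freq >= 0, min_freq < max_freq, max_freq <= 1,
            flank >= 1, intron_margin >= 0, seed_length >= 8)
  structure(list(min_freq = min_freq, max_freq = max_freq, flank = flank,
                 evalue_cutoff = evalue_cutoff,
                 strand_bias_threshold = strand_bias_threshold,
                 intron_margin = intron_margin,
                 dna_mode = match.arg(dna_mode),
                 seed_length = seed_length,
                 bias_scope = match.arg(bias_scope)),
            class = "FilterConfig")
}

#' Edit-frequency filter
#'
#' Pass iff `min_freq <= f <= max_freq` (bounds inclusive: the removal
#' rule is "below 5% and above 95%").
#'
#' @param f edit frequencies.
#' @param config a [filter_config()].
#' @return logical vector.
#' @export
frequency_filter <- function(f, config = filter_config()) {
  f >= config$min_freq & f <= config$max_freq
}

#' Strand-bias filter
#'
#' Fail iff the dominant strand carries strictly more than the threshold
#' fraction of edit-supporting reads.  Returns `NA` (not evaluable) where
#' strand counts are missing.
#'
#' @param fwd,rev per-strand edit-supporting read counts.
#' @param config a [filter_config()].
#' @return logical vector (`TRUE` = pass, `NA` = not evaluable).
#' @export
strand_bias_filter <- function(fwd, rev, config = filter_config()) {
  tot <- fwd + rev
  out <- pmax(fwd, rev) / tot <= config$strand_bias_threshold
  out[is.na(fwd) | is.na(rev) | (!is.na(tot) & tot == 0)] <- NA
  out
}

#' Intron-edge filter
#'
#' Fail iff the site lies within `intron_margin` bases (ends inclusive)
#' of either end of any annotated intron — where spliced reads mapped into
#' introns mimic editing.
#'
#' @param contig,pos site coordinates (vectorised).
#' @param gene_models named list of `GeneModel`s.
#' @param config a [filter_config()].
#' @return logical vector (`TRUE` = pass).
#' @export
intron_edge_filter <- function(contig, pos, gene_models, config = filter_config()) {
  m <- config$intron_margin
  if (m == 0) return(rep(TRUE, length(pos)))
  ## enumerate all intron-edge positions per contig once
  edge_pos <- list()
  for (g in gene_models) {
    if (nrow(g$introns) == 0) next
    p <- unlist(mapply(function(s, e) {
      c(s:min(s + m - 1L, e), max(e - m + 1L, s):e)
    }, g$introns$start, g$introns$end, SIMPLIFY = FALSE), use.names = FALSE)
    edge_pos[[g$contig]] <- c(edge_pos[[g$contig]], p)
  }
  if (!length(edge_pos)) return(rep(TRUE, length(pos)))
  out <- rep(TRUE, length(pos))
  contig <- rep_len(contig, length(pos))
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- !(pos[i] %in% (edge_pos[[ct]] %||% integer(0)))
  }
  out
}

#' DNA concordance filter
#'
#' A site passes only when DNA-seq reads unambiguously support the
#' reference: coverage >= 1 and zero non-reference reads.  In `"flagged"`
#' mode, sites with no DNA coverage pass with `zero_cov = TRUE`.
#'
#' @param sites an `EditSiteTable`.
#' @param dna_counts a DNA-seq `SiteCountTable`.
#' @param config a [filter_config()].
#' @return data.frame with logical columns `pass` and `zero_cov`.
#' @export
dna_concordance_filter <- function(sites, dna_counts, config = filter_config()) {
  key <- paste(sites$contig, sites$pos)
  dkey <- paste(dna_counts$contig, dna_counts$pos)
  idx <- match(key, dkey)
  cov <- rep(0L, nrow(sites))
  nonref <- rep(0L, nrow(sites))
  hit <- !is.na(idx)
  if (any(hit)) {
    bt <- base_totals(dna_counts)
    colnames(bt) <- BASES
    cov[hit] <- site_coverage(dna_counts)[idx[hit]]
    refn <- bt[cbind(idx[hit], match(sites$ref[hit], BASES))]
    nonref[hit] <- cov[hit] - refn
  }
  zero <- cov == 0
  pass <- cov >= 1 & nonref == 0
  if (config$dna_mode == "flagged") pass[zero] <- TRUE
  data.frame(pass = pass, zero_cov = zero)
}

## ---- uniqueness -----------------------------------------------------------

## Karlin-Altschul lambda for match +2 / mismatch -3 at uniform base
## composition; K fixed at the conventional ungapped 0.41.
ka_lambda <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 5))$root
}
KA_K <- 0.41

#' Build an exact-seed index of the genome for the uniqueness search
#'
#' Hashes every `seed_length`-mer of the genome to its positions, so
#' window uniqueness checks are O(window length).
#'
#' @param genome a `GenomeReference`.
#' @param seed_length k-mer length (default 16).
#' @return object of class `UniquenessIndex`.
#' @export
uniqueness_index <- function(genome, seed_length = 16) {
  ct <- character(0); ps <- integer(0); km <- character(0)
  for (nm in names(genome$contigs)) {
    s <- genome$contigs[[nm]]
    L <- nchar(s)
    if (L < seed_length) next
    starts <- seq_len(L - seed_length + 1L)
    kk <- substring(s, starts, starts + seed_length - 1L)
    keep <- !grepl("N", kk, fixed = TRUE)
    ct <- c(ct, rep(nm, sum(keep))); ps <- c(ps, starts[keep]); km <- c(km, kk[keep])
  }
  e <- list2env(split(seq_along(km), km), hash = TRUE,
                envir = new.env(hash = TRUE, parent = emptyenv()))
  structure(list(hash = e, contig = ct, pos = ps, k = seed_length,
                 genome_len = sum(genome$lengths)),
            class = "UniquenessIndex")
}

## best ungapped segment score of qseq vs contig sequence along one
## diagonal (qseq position j aligns with genome position diag + j)
best_diagonal_score <- function(qseq, gseq, diag, match = 2, mismatch = -3) {
  L <- nchar(qseq); G <- nchar(gseq)
  j1 <- max(1L, 1L - diag); j2 <- min(L, G - diag)
  if (j1 > j2) return(0)
  q <- strsplit(substr(qseq, j1, j2), "")[[1]]
  g <- strsplit(substr(gseq, diag + j1, diag + j2), "")[[1]]
  sc <- ifelse(q == g, match, mismatch)
  best <- 0; run <- 0
  for (x in sc) {                      # Kadane: maximal scoring segment
    run <- max(0, run + x)
    best <- max(best, run)
  }
  best
}

## qualifying (e-value <= cutoff) non-self hit for one window, one
## orientation of the query
window_has_hit <- function(qseq, genome, index, config, self_contig,
                           self_diag = NULL) {
  k <- index$k
  L <- nchar(qseq)
  if (L < k) return(FALSE)
  lambda <- ka_lambda()
  searched <- 2 * index$genome_len     # both strands
  starts <- seq_len(L - k + 1L)
  kmers <- substring(qseq, starts, starts + k - 1L)
  seen <- character(0)
  for (i in seq_along(kmers)) {
    hits <- get0(kmers[i], envir = index$hash, ifnotfound = NULL)
    if (is.null(hits)) next
    for (h in hits) {
      ct <- index$contig[h]
      diag <- index$pos[h] - starts[i]
      if (!is.null(self_diag) && ct == self_contig && diag == self_diag) next
      key <- paste(ct, diag)
      if (key %in% seen) next
      seen <- c(seen, key)
      S <- best_diagonal_score(qseq, genome$contigs[[ct]], diag)
      ev <- KA_K * L * searched * exp(-lambda * S)
      if (ev <= config$evalue_cutoff) return(TRUE)
    }
  }
  FALSE
}

#' Sequence-context uniqueness filter
#'
#' A window of `2 * flank + 1` bases centred on each site (clipped at
#' contig edges) must not match any other genomic locus.  With a BLAST
#' tabular (`-outfmt 6`) hits table, a site fails when any non-self hit
#' has e-value at or below the cutoff.  In internal mode, exact
#' `seed_length`-mer seeds (both strands) are extended ungapped
#' (match +2 / mismatch -3) and scored with a Karlin-Altschul e-value.
#'
#' @param sites an `EditSiteTable`.
#' @param genome a `GenomeReference`.
#' @param config a [filter_config()].
#' @param hits optional BLAST outfmt-6 data.frame (see
#'   [read_blast_hits()]); query ids must be `contig:start-end` window
#'   ids as produced by [uniqueness_window_ids()].
#' @param index optional prebuilt [uniqueness_index()] (built on the fly
#'   otherwise).
#' @return logical vector (`TRUE` = pass).
#' @export
uniqueness_filter <- function(sites, genome, config = filter_config(),
                              hits = NULL, index = NULL) {
  if (!nrow(sites)) return(logical(0))
  wstart <- pmax(1L, sites$pos - config$flank)
  wend <- pmin(genome$lengths[sites$contig], sites$pos + config$flank)
  if (!is.null(hits)) {
    ids <- sprintf("%s:%d-%d", sites$contig, wstart, wend)
    return(vapply(seq_len(nrow(sites)), function(i) {
      h <- hits[hits$qseqid == ids[i] & hits$evalue <= config$evalue_cutoff, ,
                drop = FALSE]
      if (!nrow(h)) return(TRUE)
      self <- h$sseqid == sites$contig[i] &
        pmin(h$sstart, h$send) <= wend[i] & pmax(h$sstart, h$send) >= wstart[i]
      !any(!self)
    }, logical(1)))
  }
  if (is.null(index)) index <- uniqueness_index(genome, config$seed_length)
  vapply(seq_len(nrow(sites)), function(i) {
    qseq <- genome_seq(genome, sites$contig[i], wstart[i], wend[i])
    fwd <- window_has_hit(qseq, genome, index, config, sites$contig[i],
                          self_diag = wstart[i] - 1L)
    if (fwd) return(FALSE)
    !window_has_hit(reverse_complement(qseq), genome, index, config,
                    sites$contig[i], self_diag = NULL)
  }, logical(1))
}

#' Window ids used to match BLAST hits back to sites
#'
#' @inheritParams uniqueness_filter
#' @return character vector `contig:start-end`.
#' @export
uniqueness_window_ids <- function(sites, genome, config = filter_config()) {
  wstart <- pmax(1L, sites$pos - config$flank)
  wend <- pmin(genome$lengths[sites$contig], sites$pos + config$flank)
  sprintf("%s:%d-%d", sites$contig, wstart, wend)
}

#' Read a BLAST tabular (outfmt 6) hits table
#'
#' @param path path to a 12-column `-outfmt 6` file.
#' @return data.frame with the standard column names (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    return(setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), cols))
  }
  h <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(h)[seq_along(cols)] <- cols
  h
}

## ---- the cascade ----------------------------------------------------------

#' Apply the full filter cascade
#'
#' Evaluates every filter on every site (flags are recorded
#' independently), then reports survivors and an audit of counts
#' remaining after each stage in fixed order: frequency, uniqueness,
#' strand bias, intron edge, DNA concordance.  A filter that cannot be
#' evaluated (missing strand counts, no DNA table) passes sites through
#' with an `NA` flag.
#'
#' @param sites an `EditSiteTable` from [call_edits()] (significant sites
#'   are filtered; pass the subset you want filtered).
#' @param genome a `GenomeReference`.
#' @param gene_models named list of `GeneModel`s.
#' @param dna_counts optional DNA-seq `SiteCountTable`.
#' @param hits optional BLAST outfmt-6 hits table (external uniqueness
#'   mode).
#' @param config a [filter_config()].
#' @param index optional prebuilt [uniqueness_index()].
#' @return list of class `FilterResult`: `sites` (input plus `pass_*`
#'   flag columns and `dna_zero_cov`), `survivors` (rows passing all
#'   evaluable filters) and `audit` (data.frame stage/remaining).
#' @export
apply_filters <- function(sites, genome, gene_models, dna_counts = NULL,
                          hits = NULL, config = filter_config(),
                          index = NULL) {
  s <- sites
  if (nrow(s)) {
    s$pass_frequency <- frequency_filter(s$f, config)
    s$pass_uniqueness <- uniqueness_filter(s, genome, config, hits, index)
    s$pass_strand_bias <- strand_bias_filter(s$edit_fwd, s$edit_rev, config)
    s$pass_intron_edge <- intron_edge_filter(s$contig, s$pos, gene_models, config)
    if (!is.null(dna_counts)) {
      dna <- dna_concordance_filter(s, dna_counts, config)
      s$pass_dna <- dna$pass
      s$dna_zero_cov <- dna$zero_cov
    } else {
      s$pass_dna <- NA
      s$dna_zero_cov <- NA
    }
  } else {
    for (cc in c("pass_frequency", "pass_uniqueness", "pass_strand_bias",
                 "pass_intron_edge", "pass_dna", "dna_zero_cov")) {
      s[[cc]] <- logical(0)
    }
  }
  stages <- c("pass_frequency", "pass_uniqueness", "pass_strand_bias",
              "pass_intron_edge", "pass_dna")
  keep <- rep(TRUE, nrow(s))
  audit <- data.frame(stage = c("input", sub("^pass_", "", stages)),
                      remaining = NA_integer_)
  audit$remaining[1] <- nrow(s)
  for (i in seq_along(stages)) {
    flag <- s[[stages[i]]]
    keep <- keep & (is.na(flag) | flag)     # NA = not evaluable, passes
    audit$remaining[i + 1] <- sum(keep)
  }
  surv <- s[keep, , drop = FALSE]
  rownames(surv) <- NULL
  structure(list(sites = s, survivors = surv, audit = audit,
                 config = config),
            class = "FilterResult")
}

#' @export
print.FilterResult <- function(x, ...) {
  cat("Filter cascade audit:\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
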