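# Expression normalization, breadth/tissue-bias classification and
# promoter sequence features (TATA-box scan, CpG-island overlap).

#' Relative log expression (RLE) normalization
#'
#' Median-of-ratios scaling: the size factor of a sample is the median, over
#' features with a positive geometric mean across samples, of the ratio of
#' the feature's value to its geometric mean. Normalized values are raw
#' values divided by the sample's size factor.
#'
#' @param mat Non-negative numeric matrix, features x samples (>= 2 samples).
#' @return List with `matrix` (normalized) and `size_factors` (named per
#'   sample).
#' @export
rle_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (any(mat < 0)) stop("expression matrix must be non-negative",
                         call. = FALSE)
  log_geo_means <- rowMeans(log(mat))
  usable <- is.finite(log_geo_means)
  if (!any(usable)) {
    stop("no feature has a positive geometric mean across samples",
         call. = FALSE)
  }
  geo <- exp(log_geo_means[usable])
  sf <- apply(mat, 2L, function(col) {
    stats::median(col[usable] / geo)
  })
  list(matrix = sweep(mat, 2L, sf, "/"), size_factors = sf)
}

#' Average expression over biological replicates
#'
#' @param mat Normalized expression matrix, promoters x samples.
#' @param sheet Sample sheet matching the matrix columns.
#' @return Numeric matrix, promoters x replicate groups (column order =
#'   first appearance in the sheet).
#' @export
average_replicates <- function(mat, sheet) {
  stopifnot(ncol(mat) == nrow(sheet))
  groups <- unique(sheet$replicate_group)
  out <- vapply(groups, function(g) {
    rowMeans(mat[, sheet$replicate_group == g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(mat), groups))
  colnames(out) <- groups
  out
}

#' Per-tissue mean expression
#'
#' Replicate-averaged expression summarised per tissue type (one column per
#' tissue; a tissue with several replicate groups is averaged over them).
#'
#' @param mat Normalized expression matrix, promoters x samples.
#' @param sheet Sample sheet matching the matrix columns.
#' @return Matrix, promoters x tissue types.
#' @export
tissue_means <- function(mat, sheet) {
  rep_means <- average_replicates(mat, sheet)
  grp_tissue <- sheet$tissue_type[match(colnames(rep_means),
                                        sheet$replicate_group)]
  tissues <- unique(grp_tissue)
  out <- vapply(tissues, function(tt) {
    rowMeans(rep_means[, grp_tissue == tt, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(mat), tissues))
  colnames(out) <- tissues
  out
}

#' Classify expression breadth and tissue bias
#'
#' A promoter is tissue-restricted iff its median TPM across tissue types is
#' zero (within a small numerical tolerance), otherwise broadly expressed.
#' A broad promoter is biased toward a tissue when the tissue mean is at
#' least five times the cross-tissue median (inclusive boundary); a
#' restricted promoter is biased toward a tissue when its mean TPM there
#' exceeds 1. Biased categories are the tissue categories of the biased
#' tissues. A housekeeping flag (expressed above zero in every tissue type)
#' is reported alongside.
#'
#' @param tmeans Matrix of per-tissue mean TPM, promoters x tissues.
#' @param tissue_categories Named character vector mapping tissue type to
#'   category (testis/immunity/brain/other).
#' @param bias_factor Fold-over-median threshold for broad promoters
#'   (default 5).
#' @param restricted_floor Absolute TPM threshold for restricted promoters
#'   (default 1).
#' @return Data.frame (one row per promoter): `promoter_id`, `breadth`,
#'   `median_tpm`, `max_tpm`, `biased_tissues`, `biased_categories`
#'   (comma-separated), `housekeeping`.
#' @export
classify_breadth_and_bias <- function(tmeans, tissue_categories,
                                      bias_factor = 5,
                                      restricted_floor = 1) {
  if (ncol(tmeans) == 0L) stop("no tissue means provided", call. = FALSE)
  med <- apply(tmeans, 1L, stats::median)
  mx <- apply(tmeans, 1L, max)
  restricted <- med <= 1e-9
  tissues <- colnames(tmeans)
  cats <- tissue_categories[tissues]
  biased <- matrix(FALSE, nrow(tmeans), ncol(tmeans))
  biased[restricted, ] <- tmeans[restricted, , drop = FALSE] >
    restricted_floor
  broad_idx <- which(!restricted)
  if (length(broad_idx) > 0L) {
    biased[broad_idx, ] <- tmeans[broad_idx, , drop = FALSE] >=
      bias_factor * med[broad_idx]
  }
  collapse <- function(i, labels) {
    hit <- labels[biased[i, ]]
    paste(sort(unique(hit)), collapse = ",")
  }
  n <- nrow(tmeans)
  data.frame(
    promoter_id = rownames(tmeans) %||% as.character(seq_len(n)),
    breadth = ifelse(restricted, "tissue_restricted", "broad"),
    median_tpm = med,
    max_tpm = mx,
    biased_tissues = vapply(seq_len(n), collapse, character(1),
                            labels = tissues),
    biased_categories = vapply(seq_len(n), collapse, character(1),
                               labels = cats),
    housekeeping = apply(tmeans > 0, 1L, all),
    stringsAsFactors = FALSE
  )
}

#' Build per-species expression profiles from a raw matrix
#'
#' Convenience wrapper: RLE-normalize, average replicates per tissue type,
#' then classify breadth and bias.
#'
#' @param mat Raw expression matrix (promoters x samples).
#' @param sheet Sample sheet matching the columns.
#' @inheritParams classify_breadth_and_bias
#' @return Profile data.frame (see [classify_breadth_and_bias()]) with a
#'   `species` column, plus attribute `tissue_means`.
#' @export
expression_profiles <- function(mat, sheet, bias_factor = 5,
                                restricted_floor = 1) {
  norm <- rle_normalize(mat)
  tm <- tissue_means(norm$matrix, sheet)
  cats <- tapply(sheet$tissue_category, sheet$tissue_type, function(x) x[1L])
  prof <- classify_breadth_and_bias(tm, cats, bias_factor, restricted_floor)
  prof$species <- sheet$species[1L]
  attr(prof, "tissue_means") <- tm
  attr(prof, "size_factors") <- norm$size_factors
  prof
}

# Split a comma-separated bias field back into a character set.
split_tissues <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",")[[1L]]
}

#' Motif-scan configuration
#'
#' @param window_start_offset,window_end_offset Bounds (nt upstream of the
#'   promoter start) of the scanned window; defaults 20 and 30.
#' @param p_threshold Match P-value cutoff (default 1e-3).
#' @param both_strands Scan both strands of the window (default TRUE).
#' @param background Background base composition, named A/C/G/T.
#' @return List of class `motif_config`.
#' @export
motif_config <- function(window_start_offset = 20L,
                         window_end_offset = 30L,
                         p_threshold = 1e-3,
                         both_strands = TRUE,
                         background = c(A = 0.25, C = 0.25,
                                        G = 0.25, T = 0.25)) {
  stopifnot(window_start_offset < window_end_offset,
            p_threshold > 0, p_threshold < 1,
            abs(sum(background) - 1) < 1e-8)
  structure(list(window_start_offset = as.integer(window_start_offset),
                 window_end_offset = as.integer(window_end_offset),
                 p_threshold = p_threshold,
                 both_strands = isTRUE(both_strands),
                 background = background),
            class = "motif_config")
}

#' Load the bundled synthetic TBP-like TATA position weight matrix
#'
#' A small hand-constructed count matrix with the canonical TATAWAWR shape;
#' it is a synthetic stand-in for a curated TBP matrix, shipped so the scan
#' is reproducible without external motif databases.
#'
#' @return A 4 x width numeric matrix of base counts (rows A, C, G, T).
#' @export
default_tata_pwm <- function() {
  path <- system.file("extdata", "tata_synthetic.pwm",
                      package = "promoterTurnover")
  read_pwm(path)
}

#' Read a position weight matrix file
#' @param path TSV: four rows labelled A/C/G/T, one column per position.
#' @return Numeric matrix of counts/weights with rownames A, C, G, T.
#' @export
read_pwm <- function(path) {
  df <- utils::read.table(path, header = FALSE, row.names = 1L,
                          comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df)
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- NULL
  m
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

# Log-odds score matrix from counts under a background composition.
pwm_log_odds <- function(pwm, background, pseudocount = 0.5) {
  probs <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  log2(sweep(probs, 1L, background[rownames(probs)], "/"))
}

# Exact score distribution under an i.i.d. background, by enumeration of all
# k-mers. Returns sorted unique scores with P(score >= s).
pwm_score_distribution <- function(lo, background) {
  w <- ncol(lo)
  scores <- 0
  probs <- 1
  for (j in seq_len(w)) {
    scores <- outer(scores, lo[, j], "+")
    probs <- outer(probs, background, "*")
    scores <- as.numeric(scores)
    probs <- as.numeric(probs)
  }
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  probs <- probs[ord]
  list(score = scores, p_ge = cumsum(probs))
}

# P(score >= s) under the background; exact by construction.
pwm_score_pvalue <- function(s, dist) {
  idx <- findInterval(-(s - 1e-12), -dist$score)
  if (idx == 0L) 0 else dist$p_ge[idx]
}

score_kmer <- function(kmer, lo) {
  bases <- match(strsplit(kmer, "", fixed = TRUE)[[1L]], rownames(lo))
  if (anyNA(bases)) return(-Inf)
  sum(lo[cbind(bases, seq_along(bases))])
}

#' Scan for a TATA box upstream of a promoter
#'
#' Scans the 20–30 nt window upstream of the promoter start (in transcription
#' orientation) for PWM matches on either strand. A hit is counted when the
#' exact match P-value — the probability of an equal-or-better score under
#' the i.i.d. background composition, computed by exhaustive enumeration of
#' all k-mers — is at or below the threshold and the match start lies within
#' the window.
#'
#' @param seq Nucleotide sequence covering the promoter and upstream flank,
#'   in genome (+) orientation.
#' @param promoter_offset 1-based index in `seq` of the promoter's 5' base
#'   (for "-"-strand promoters, the genomically last promoter base).
#' @param strand Promoter strand, "+" or "-".
#' @param pwm Count matrix (rows A/C/G/T); default the bundled TATA matrix.
#' @param config A [motif_config()].
#' @return List with `has_tata` (logical) and `hits` (data.frame of
#'   upstream distance, window strand, score, p_value).
#' @export
scan_tata <- function(seq, promoter_offset, strand = "+",
                      pwm = default_tata_pwm(), config = motif_config()) {
  stopifnot(length(seq) == 1L, is.character(seq))
  seq <- toupper(seq)
  n <- nchar(seq)
  if (strand == "-") {
    seq <- revcomp(seq)
    promoter_offset <- n - promoter_offset + 1L
  } else if (strand != "+") {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  w <- ncol(pwm)
  d_min <- config$window_start_offset
  d_max <- config$window_end_offset
  starts <- (promoter_offset - d_max):(promoter_offset - d_min)
  if (min(starts) < 1L || max(starts) + w - 1L > n) {
    stop("upstream scan window extends past the sequence boundary",
         call. = FALSE)
  }
  lo <- pwm_log_odds(pwm, config$background)
  dist <- pwm_score_distribution(lo, config$background)
  hits <- list()
  for (s in starts) {
    kmer <- substr(seq, s, s + w - 1L)
    cands <- list(c(kmer, "+"))
    if (config$both_strands) cands <- c(cands, list(c(revcomp(kmer), "-")))
    for (cand in cands) {
      sc <- score_kmer(cand[1L], lo)
      if (!is.finite(sc)) next
      p <- pwm_score_pvalue(sc, dist)
      if (p <= config$p_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          upstream_distance = promoter_offset - s,
          match_strand = cand[2L], score = sc, p_value = p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(upstream_distance = integer(), match_strand = character(),
               score = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  list(has_tata = nrow(hits) > 0L, hits = hits)
}

#' Flag promoters overlapping CpG islands
#'
#' Any overlap of at least one base counts; half-open intervals that merely
#' abut do not overlap.
#'
#' @param promoters Promoter data.frame (chrom/start/end).
#' @param cpg_islands Interval data.frame (chrom/start/end); may be empty.
#' @return Logical vector, one flag per promoter.
#' @export
label_cpg_overlap <- function(promoters, cpg_islands) {
  if (nrow(promoters) == 0L) return(logical(0))
  if (is.null(cpg_islands) || nrow(cpg_islands) == 0L) {
    return(rep(FALSE, nrow(promoters)))
  }
  overlap_counts(promoters, cpg_islands) > 0L
}
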