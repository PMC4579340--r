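# Permutation and bootstrap machinery: mappability-aware interval
# permutation nulls, repeat-density enrichment around oriented promoter
# anchors, and strand-oriented window profiles over a per-base score track.

#' Window-profile configuration
#'
#' @param flank Bases each side of the promoter anchor (default 1000); must
#'   be divisible by `window`.
#' @param window Window width in bases (default 50).
#' @param orient_by_strand Flip the profile for minus-strand anchors so the
#'   x-axis follows the direction of transcription (default TRUE).
#' @return List of class `profile_config`.
#' @export
profile_config <- function(flank = 1000L, window = 50L,
                           orient_by_strand = TRUE) {
  flank <- as.integer(flank)
  window <- as.integer(window)
  stopifnot(flank > 0L, window > 0L, flank %% window == 0L)
  structure(list(flank = flank, window = window,
                 orient_by_strand = isTRUE(orient_by_strand)),
            class = "profile_config")
}

#' Compute the allowed placement regions for permutation
#'
#' Mappable regions minus blacklisted regions, as a flattened interval set.
#'
#' @param mappable,blacklist Interval data.frames (chrom/start/end);
#'   `blacklist` may be NULL or empty.
#' @return Data.frame of disjoint allowed intervals.
#' @export
allowed_regions <- function(mappable, blacklist = NULL) {
  gm <- GenomicRanges::reduce(intervals_to_granges(mappable,
                                                   use_strand = FALSE))
  if (!is.null(blacklist) && nrow(blacklist) > 0L) {
    gb <- GenomicRanges::reduce(intervals_to_granges(blacklist,
                                                     use_strand = FALSE))
    gm <- GenomicRanges::setdiff(gm, gb)
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gm)),
    start = GenomicRanges::start(gm) - 1L,
    end = GenomicRanges::end(gm),
    stringsAsFactors = FALSE
  )
}

#' Permute interval positions within allowed regions
#'
#' Places each interval, with its length preserved, uniformly at random over
#' every valid start position inside the allowed regions (optionally
#' restricted to the interval's source chromosome). Permuted intervals may
#' overlap one another; placement is rejection-free and unbiased over valid
#' starts.
#'
#' @param intervals Interval data.frame (chrom/start/end, optional
#'   name/strand).
#' @param allowed Allowed-region data.frame, e.g. from [allowed_regions()].
#' @param n_permutations Number of permuted interval sets (default 1000).
#' @param seed Integer seed (optional).
#' @param per_chromosome Keep every interval on its source chromosome
#'   (default FALSE).
#' @return Data.frame of permuted intervals with a `perm` index column.
#' @export
permute_intervals <- function(intervals, allowed, n_permutations = 1000L,
                              seed = NULL, per_chromosome = FALSE) {
  stopifnot(nrow(allowed) > 0L)
  n <- nrow(intervals)
  if (n == 0L) stop("no intervals to permute", call. = FALSE)
  len <- intervals$end - intervals$start
  with_seed(seed, {
    out_chrom <- character(n * n_permutations)
    out_start <- integer(n * n_permutations)
    for (i in seq_len(n)) {
      regions <- if (per_chromosome) {
        allowed[allowed$chrom == intervals$chrom[i], , drop = FALSE]
      } else {
        allowed
      }
      valid <- regions$end - regions$start - len[i] + 1L
      ok <- valid > 0L
      if (!any(ok)) {
        id <- if ("name" %in% names(intervals)) intervals$name[i] else i
        stop("interval '", id, "' (length ", len[i],
             ") does not fit inside any allowed region", call. = FALSE)
      }
      regions <- regions[ok, , drop = FALSE]
      valid <- valid[ok]
      ridx <- sample.int(nrow(regions), n_permutations, replace = TRUE,
                         prob = valid)
      offs <- floor(stats::runif(n_permutations) * valid[ridx])
      slot <- seq(i, by = n, length.out = n_permutations)
      out_chrom[slot] <- regions$chrom[ridx]
      out_start[slot] <- regions$start[ridx] + as.integer(offs)
    }
    perm <- rep(seq_len(n_permutations), each = n)
    data.frame(
      perm = perm,
      chrom = out_chrom,
      start = out_start,
      end = out_start + rep(len, n_permutations),
      name = if ("name" %in% names(intervals)) {
        rep(intervals$name, n_permutations)
      } else {
        rep(as.character(seq_len(n)), n_permutations)
      },
      strand = if ("strand" %in% names(intervals)) {
        rep(intervals$strand, n_permutations)
      } else {
        "."
      },
      stringsAsFactors = FALSE
    )
  })
}

# Expand a bedGraph data.frame into per-chromosome numeric vectors
# (NA where the track is silent). Internal.
track_vectors <- function(track) {
  out <- list()
  for (cc in unique(track$chrom)) {
    rows <- track[track$chrom == cc, , drop = FALSE]
    vec <- rep(NA_real_, max(rows$end))
    idx <- sequence(rows$end - rows$start, from = rows$start + 1L)
    vec[idx] <- rep(rows$score, rows$end - rows$start)
    out[[cc]] <- vec
  }
  out
}

# Per-anchor x per-position matrix of track values around oriented anchors.
# Anchor = the interval's 5' boundary in transcription orientation.
anchor_value_matrix <- function(anchors, vecs, flank, orient = TRUE) {
  n <- nrow(anchors)
  offs <- seq(-flank, flank - 1L)
  minus <- orient & anchors$strand == "-"
  a <- ifelse(minus, anchors$end - 1L, anchors$start)
  m <- matrix(NA_real_, n, length(offs))
  for (i in seq_len(n)) {
    vec <- vecs[[anchors$chrom[i]]]
    if (is.null(vec)) next
    g <- if (minus[i]) a[i] - offs else a[i] + offs
    inb <- g >= 0L & g < length(vec)
    vals <- rep(NA_real_, length(offs))
    vals[inb] <- vec[g[inb] + 1L]
    m[i, ] <- vals
  }
  m
}

# Collapse a per-position anchor matrix to per-window means:
# per anchor, mean over usable bases in each window; then mean over anchors.
window_profile <- function(m, flank, window) {
  n_win <- (2L * flank) %/% window
  win_id <- rep(seq_len(n_win), each = window)
  anchor_win <- t(apply(m, 1L, function(row) {
    tapply(row, win_id, function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
  }))
  if (nrow(m) == 1L) anchor_win <- matrix(anchor_win, nrow = 1L)
  prof <- colMeans(anchor_win, na.rm = TRUE)
  prof[!is.finite(prof)] <- NA_real_
  usable <- colSums(!is.na(anchor_win))
  list(profile = unname(prof), n_usable_anchors = unname(usable),
       offsets = seq(-flank, flank - window, by = window),
       anchor_windows = anchor_win)
}

#' Strand-oriented window profile of a per-base score track
#'
#' Mean score in fixed windows around the oriented 5' anchor of each
#' interval (mean over anchors of per-window means), with an optional
#' permutation null curve from length-preserving placement of the anchors
#' within allowed regions. Bases not covered by the track are excluded from
#' means and counted; a window with no usable bases across all anchors is
#' reported missing.
#'
#' @param anchors Interval data.frame (chrom/start/end/strand).
#' @param track bedGraph data.frame of per-base scores.
#' @param config A [profile_config()].
#' @param null Optional list with `allowed` (regions), `n_permutations`,
#'   `seed` — when supplied, a permutation null curve and 95% band are
#'   computed.
#' @return List of class `score_profile`: `offsets`, `observed`,
#'   `n_usable_anchors`, and optionally `null_mean`, `null_ci_low`,
#'   `null_ci_high`.
#' @export
score_profile <- function(anchors, track, config = profile_config(),
                          null = NULL) {
  stopifnot(nrow(anchors) > 0L)
  vecs <- track_vectors(track)
  m <- anchor_value_matrix(anchors, vecs, config$flank,
                           config$orient_by_strand)
  wp <- window_profile(m, config$flank, config$window)
  res <- list(offsets = wp$offsets, observed = wp$profile,
              n_usable_anchors = wp$n_usable_anchors,
              config = config)
  if (!is.null(null)) {
    n_perm <- null$n_permutations %||% 100L
    perms <- permute_intervals(anchors, null$allowed,
                               n_permutations = n_perm,
                               seed = null$seed %||% NULL)
    curves <- vapply(seq_len(n_perm), function(p) {
      pa <- perms[perms$perm == p, , drop = FALSE]
      pm <- anchor_value_matrix(pa, vecs, config$flank,
                                config$orient_by_strand)
      window_profile(pm, config$flank, config$window)$profile
    }, numeric(length(wp$profile)))
    if (length(wp$profile) == 1L) curves <- matrix(curves, nrow = 1L)
    res$null_mean <- rowMeans(curves, na.rm = TRUE)
    res$null_ci_low <- apply(curves, 1L, stats::quantile, probs = 0.025,
                             na.rm = TRUE, names = FALSE)
    res$null_ci_high <- apply(curves, 1L, stats::quantile, probs = 0.975,
                              na.rm = TRUE, names = FALSE)
  }
  class(res) <- "score_profile"
  res
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile: ", length(x$offsets), " windows of ",
      x$config$window, " bp (flank ", x$config$flank, " bp)\n", sep = "")
  cat(sprintf("  mean observed score %.3f (range %.3f to %.3f)\n",
              mean(x$observed, na.rm = TRUE),
              min(x$observed, na.rm = TRUE),
              max(x$observed, na.rm = TRUE)))
  if (!is.null(x$null_mean)) {
    cat(sprintf("  permutation null mean %.3f\n",
                mean(x$null_mean, na.rm = TRUE)))
  }
  invisible(x)
}

# Binary coverage track (1 where covered by any repeat) per chromosome,
# sized to cover the given intervals.
coverage_track <- function(repeats, extent) {
  rows <- list()
  for (cc in unique(extent$chrom)) {
    size <- max(extent$end[extent$chrom == cc]) + 1L
    rr <- repeats[repeats$chrom == cc, , drop = FALSE]
    vec <- rep(0, size)
    if (nrow(rr) > 0L) {
      idx <- sequence(pmin(rr$end, size) - rr$start,
                      from = rr$start + 1L)
      vec[idx] <- 1
    }
    rows[[cc]] <- vec
  }
  rows
}

#' Repeat enrichment around promoter anchors
#'
#' The statistic is the fraction of bases covered by repeats in fixed
#' windows around the oriented promoter anchor, compared against a
#' background: either a set of conserved promoters (same statistic) or
#' permuted placements of the promoters themselves within allowed regions.
#' A bootstrap 95% CI over the promoter set is attached to the overall
#' fold, and a per-family table reports the fraction of promoters with at
#' least 1 bp of overlap by each repeat family.
#'
#' @param promoters Promoter interval data.frame (chrom/start/end/strand).
#' @param repeats Repeat data.frame (chrom/start/end) with a `family`
#'   column.
#' @param background Either "conserved_promoters" (requires
#'   `background_set`) or "permuted_insertions" (requires `allowed`).
#' @param background_set Interval data.frame for the conserved-promoter
#'   background.
#' @param allowed Allowed regions for the permutation background.
#' @param config A [profile_config()].
#' @param n_permutations,n_boot,seed Permutation/bootstrap controls.
#' @return List of class `repeat_enrichment`: per-window observed and
#'   background coverage and fold, overall fold with bootstrap and
#'   permutation-null CIs, and the per-family frequency table.
#' @export
repeat_enrichment <- function(promoters, repeats,
                              background = c("permuted_insertions",
                                             "conserved_promoters"),
                              background_set = NULL, allowed = NULL,
                              config = profile_config(),
                              n_permutations = 200L, n_boot = 1000L,
                              seed = NULL) {
  background <- match.arg(background)
  if (nrow(promoters) == 0L) stop("empty promoter set", call. = FALSE)
  extent <- rbind(
    promoters[, c("chrom", "start", "end")],
    if (!is.null(background_set)) background_set[, c("chrom", "start",
                                                     "end")],
    if (!is.null(allowed)) allowed[, c("chrom", "start", "end")],
    repeats[, c("chrom", "start", "end")]
  )
  extent$end <- extent$end + config$flank
  vecs <- coverage_track(repeats, extent)

  m <- anchor_value_matrix(promoters, vecs, config$flank,
                           config$orient_by_strand)
  wp <- window_profile(m, config$flank, config$window)
  observed <- wp$profile
  overall_obs <- mean(rowMeans(m, na.rm = TRUE), na.rm = TRUE)

  boot <- with_seed(derive_seed(seed, 1L), {
    anchor_means <- rowMeans(m, na.rm = TRUE)
    reps <- vapply(seq_len(n_boot), function(b) {
      mean(anchor_means[sample.int(length(anchor_means),
                                   replace = TRUE)], na.rm = TRUE)
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })

  if (background == "conserved_promoters") {
    stopifnot(!is.null(background_set), nrow(background_set) > 0L)
    bm <- anchor_value_matrix(background_set, vecs, config$flank,
                              config$orient_by_strand)
    bg_profile <- window_profile(bm, config$flank, config$window)$profile
    bg_overall <- mean(rowMeans(bm, na.rm = TRUE), na.rm = TRUE)
    null_ci <- c(NA_real_, NA_real_)
  } else {
    stopifnot(!is.null(allowed))
    perms <- permute_intervals(promoters, allowed,
                               n_permutations = n_permutations,
                               seed = derive_seed(seed, 2L))
    perm_overall <- numeric(n_permutations)
    curves <- matrix(NA_real_, n_permutations, length(observed))
    for (p in seq_len(n_permutations)) {
      pa <- perms[perms$perm == p, , drop = FALSE]
      pm <- anchor_value_matrix(pa, vecs, config$flank,
                                config$orient_by_strand)
      curves[p, ] <- window_profile(pm, config$flank, config$window)$profile
      perm_overall[p] <- mean(rowMeans(pm, na.rm = TRUE), na.rm = TRUE)
    }
    bg_profile <- colMeans(curves, na.rm = TRUE)
    bg_overall <- mean(perm_overall)
    null_ci <- stats::quantile(perm_overall, c(0.025, 0.975),
                               names = FALSE)
  }

  fam <- family_frequency(promoters, repeats)

  structure(list(
    windows = data.frame(
      offset = wp$offsets,
      observed = observed,
      background = bg_profile,
      fold = ifelse(bg_profile > 0, observed / bg_profile,
                    ifelse(observed > 0, Inf, 0))
    ),
    observed = overall_obs,
    null_mean = bg_overall,
    null_ci = null_ci,
    fold = if (bg_overall > 0) overall_obs / bg_overall else
      ifelse(overall_obs > 0, Inf, 0),
    bootstrap_ci = boot,
    family_frequency = fam,
    background = background,
    n_promoters = nrow(promoters)
  ), class = "repeat_enrichment")
}

#' @export
print.repeat_enrichment <- function(x, ...) {
  cat("Repeat enrichment over", x$n_promoters, "promoters vs",
      x$background, "\n")
  cat(sprintf("  coverage %.3f vs background %.3f: fold %.2f (boot CI %.3f-%.3f)\n",
              x$observed, x$null_mean, x$fold, x$bootstrap_ci[1L],
              x$bootstrap_ci[2L]))
  invisible(x)
}

#' Per-family repeat overlap frequency
#'
#' @param promoters Promoter interval data.frame.
#' @param repeats Repeat data.frame with a `family` column.
#' @return Data.frame: family, n_overlapping, frequency (fraction of
#'   promoters with >= 1 bp overlap by that family).
#' @export
family_frequency <- function(promoters, repeats) {
  families <- sort(unique(repeats$family))
  if (length(families) == 0L || nrow(promoters) == 0L) {
    return(data.frame(family = character(), n_overlapping = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(families, function(ff) {
    n <- sum(overlap_counts(promoters,
                            repeats[repeats$family == ff, ,
                                    drop = FALSE]) > 0L)
    data.frame(family = ff, n_overlapping = n,
               frequency = n / nrow(promoters), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bootstrap a proportion with a percentile confidence interval
#'
#' @param flags Logical vector of membership flags (n >= 1).
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed (optional).
#' @param level Confidence level (default 0.95).
#' @return List: `proportion`, `ci_low`, `ci_high`, `n`, `n_boot`.
#' @export
bootstrap_proportion <- function(flags, n_boot = 1000L, seed = NULL,
                                 level = 0.95) {
  stopifnot(length(flags) >= 1L, is.logical(flags))
  p <- mean(flags)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(flags[sample.int(length(flags), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(proportion = p, ci_low = ci[1L], ci_high = ci[2L],
       n = length(flags), n_boot = n_boot)
}
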