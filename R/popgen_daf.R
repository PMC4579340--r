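# Derived-allele-frequency constraint test: polarization, frequency
# binning, exact 2x2 test against a genome-wide reference, and rare
# threshold calibration.

#' DAF test configuration
#'
#' Derived alleles are "rare" strictly below `rare_max` (default 1.5%) and
#' "nonrare" strictly above `nonrare_min` (default 5%); intermediate
#' frequencies — and values exactly at a bound — are excluded.
#'
#' @param rare_max Exclusive upper bound for rare derived alleles.
#' @param nonrare_min Exclusive lower bound for nonrare derived alleles.
#' @return List of class `daf_config`.
#' @export
daf_config <- function(rare_max = 0.015, nonrare_min = 0.05) {
  stopifnot(rare_max > 0, rare_max < nonrare_min, nonrare_min < 1)
  structure(list(rare_max = rare_max, nonrare_min = nonrare_min),
            class = "daf_config")
}

#' Polarize variants into ancestral/derived alleles
#'
#' When the ancestral allele equals the reference, the derived allele is the
#' alternate and the derived frequency is the alternate frequency; when it
#' equals the alternate, alleles swap and the frequency is complemented.
#' Variants whose ancestral state is unresolved or matches neither allele
#' are discarded with a counter.
#'
#' @param variants Variant data.frame as from [read_variants()].
#' @return Data.frame of polarized variants with `derived_allele` and `daf`
#'   columns; attribute `n_unpolarized` counts discards.
#' @export
polarize <- function(variants) {
  if (is.null(variants$unresolved)) {
    variants$unresolved <- !variants$ancestral %in% c("A", "C", "G", "T")
  }
  anc_is_ref <- variants$ancestral == variants$ref
  anc_is_alt <- variants$ancestral == variants$alt
  keep <- (anc_is_ref | anc_is_alt) & !variants$unresolved
  out <- variants[keep, , drop = FALSE]
  ref_anc <- anc_is_ref[keep]
  out$derived_allele <- ifelse(ref_anc, out$alt, out$ref)
  out$daf <- ifelse(ref_anc, out$alt_frequency, 1 - out$alt_frequency)
  rownames(out) <- NULL
  attr(out, "n_unpolarized") <- sum(!keep)
  out
}

#' Bin derived allele frequencies
#' @param daf Numeric vector of derived allele frequencies.
#' @param config A [daf_config()].
#' @return Character vector: "rare", "nonrare", or NA (excluded).
#' @export
bin_daf <- function(daf, config = daf_config()) {
  ifelse(daf < config$rare_max, "rare",
         ifelse(daf > config$nonrare_min, "nonrare", NA_character_))
}

#' Two-sided exact test on a 2x2 table
#'
#' Conditional (hypergeometric) exact test: the p-value is the sum of
#' probabilities of all tables with the same margins that are no more
#' probable than the observed table (with the conventional small relative
#' tolerance for numerically tied tables).
#'
#' @param a,b,c,d Counts: test rare/nonrare, reference rare/nonrare.
#' @return The two-sided p-value.
#' @export
exact_test_2x2 <- function(a, b, c, d) {
  m <- a + c          # rare margin
  n <- b + d          # nonrare margin
  k <- a + b          # test margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- dens[a - lo + 1L]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

woolf_ci <- function(a, b, c, d, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(c(lor - z * se, lor + z * se))
}

#' Derived-allele-frequency constraint test
#'
#' Bins the derived allele frequencies of variants overlapping a test
#' interval set into rare/nonrare and compares the rare:nonrare ratio to
#' fixed genome-wide reference counts with a two-sided exact test. The
#' reported odds ratio is the sample ratio of ratios; the 95% CI is the
#' exact conditional interval for moderate counts and the logit-normal
#' (Woolf) approximation when the table total exceeds `exact_ci_max`
#' (recorded in `ci_method`). A variant overlapping several test intervals
#' counts once (the interval set is flattened).
#'
#' @param test_intervals Interval data.frame (chrom/start/end) of the test
#'   set.
#' @param variants Variant data.frame (raw; polarization is applied here).
#' @param reference_counts Numeric `(ref_rare, ref_nonrare)`, both > 0.
#' @param config A [daf_config()].
#' @param exact_ci_max Largest table total for which the exact conditional
#'   CI is computed (default 10000).
#' @return Object of class `daf_result`.
#' @export
daf_test <- function(test_intervals, variants, reference_counts,
                     config = daf_config(), exact_ci_max = 10000) {
  stopifnot(length(reference_counts) == 2L, all(reference_counts > 0))
  pol <- polarize(variants)
  if (nrow(test_intervals) > 0L && nrow(pol) > 0L) {
    ti <- GenomicRanges::reduce(intervals_to_granges(test_intervals,
                                                     use_strand = FALSE))
    vg <- GenomicRanges::GRanges(pol$chrom,
                                 IRanges::IRanges(pol$pos + 1L, pol$pos + 1L))
    h <- harmonize_seqlevels(vg, ti)
    inside <- GenomicRanges::countOverlaps(h[[1L]], h[[2L]]) > 0L
  } else {
    inside <- rep(FALSE, nrow(pol))
  }
  daf <- pol$daf[inside]
  bins <- bin_daf(daf, config)
  a <- sum(bins == "rare", na.rm = TRUE)
  b <- sum(bins == "nonrare", na.rm = TRUE)
  r <- reference_counts[1L]
  s <- reference_counts[2L]
  n_informative <- a + b
  uninformative <- n_informative == 0L
  or <- if (b == 0 || uninformative) {
    if (a > 0) Inf else NA_real_
  } else {
    (a / b) / (r / s)
  }
  p <- if (uninformative) NA_real_ else exact_test_2x2(a, b, r, s)
  total <- a + b + r + s
  if (uninformative) {
    ci <- c(NA_real_, NA_real_)
    ci_method <- "none"
  } else if (a == 0 || b == 0) {
    ft <- stats::fisher.test(matrix(c(a, b, r, s), 2L, byrow = TRUE))
    ci <- ft$conf.int
    ci_method <- "exact_conditional"
  } else if (total <= exact_ci_max) {
    ft <- stats::fisher.test(matrix(c(a, b, r, s), 2L, byrow = TRUE))
    ci <- ft$conf.int
    ci_method <- "exact_conditional"
  } else {
    ci <- woolf_ci(a, b, r, s)
    ci_method <- "logit_normal"
  }
  structure(list(
    test_rare = a, test_nonrare = b,
    ref_rare = r, ref_nonrare = s,
    odds_ratio = or, ci_low = ci[1L], ci_high = ci[2L],
    p_value = p, n_informative = n_informative,
    n_overlapping = sum(inside),
    n_unpolarized = attr(pol, "n_unpolarized"),
    uninformative = uninformative,
    ci_method = ci_method, config = config
  ), class = "daf_result")
}

#' @export
print.daf_result <- function(x, ...) {
  cat("Derived allele frequency constraint test\n")
  cat(sprintf("  test set: %d rare, %d nonrare (n informative = %d)\n",
              x$test_rare, x$test_nonrare, x$n_informative))
  cat(sprintf("  reference: %d rare, %d nonrare\n", x$ref_rare,
              x$ref_nonrare))
  if (x$uninformative) {
    cat("  no informative variants in the test set\n")
  } else {
    cat(sprintf("  odds ratio = %.3f [%.3f, %.3f] (%s CI), p = %.3g\n",
                x$odds_ratio, x$ci_low, x$ci_high, x$ci_method,
                x$p_value))
  }
  invisible(x)
}

#' Calibrate the rare-frequency threshold
#'
#' For each candidate rare threshold, runs the constraint test of a
#' constrained variant set against a neutral set (with a fixed nonrare
#' bound) and chooses the candidate maximizing the log odds ratio divided
#' by its standard error (taken from the log-scale CI width) — an explicit,
#' scale-free operationalization of "maximize the odds ratio while
#' minimizing the confidence interval". When no candidate's CI excludes 1,
#' the selection is degenerate and the lowest candidate is returned with a
#' flag. The full table is always emitted.
#'
#' @param constrained_daf,neutral_daf Numeric vectors of derived allele
#'   frequencies (already polarized).
#' @param candidates Numeric vector of candidate rare thresholds.
#' @param nonrare_min Fixed nonrare bound (default 0.05).
#' @return List: `chosen`, `degenerate`, `table` (candidate, counts, OR,
#'   CI, score).
#' @export
calibrate_rare_threshold <- function(constrained_daf, neutral_daf,
                                     candidates, nonrare_min = 0.05) {
  if (length(candidates) == 0L) stop("no candidate thresholds supplied",
                                     call. = FALSE)
  candidates <- sort(candidates[candidates < nonrare_min])
  if (length(candidates) == 0L) {
    stop("no candidate threshold lies below the nonrare bound",
         call. = FALSE)
  }
  rows <- lapply(candidates, function(r) {
    cfg <- daf_config(rare_max = r, nonrare_min = nonrare_min)
    a <- sum(bin_daf(constrained_daf, cfg) == "rare", na.rm = TRUE)
    b <- sum(bin_daf(constrained_daf, cfg) == "nonrare", na.rm = TRUE)
    cc <- sum(bin_daf(neutral_daf, cfg) == "rare", na.rm = TRUE)
    d <- sum(bin_daf(neutral_daf, cfg) == "nonrare", na.rm = TRUE)
    if (any(c(a, b, cc, d) == 0)) {
      return(data.frame(rare_max = r, test_rare = a, test_nonrare = b,
                        ref_rare = cc, ref_nonrare = d, odds_ratio =
                          NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        score = NA_real_, stringsAsFactors = FALSE))
    }
    or <- (a / b) / (cc / d)
    ci <- if (a + b + cc + d <= 10000) {
      stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$conf.int
    } else {
      woolf_ci(a, b, cc, d)
    }
    se_log <- (log(ci[2L]) - log(ci[1L])) / (2 * stats::qnorm(0.975))
    data.frame(rare_max = r, test_rare = a, test_nonrare = b,
               ref_rare = cc, ref_nonrare = d, odds_ratio = or,
               ci_low = ci[1L], ci_high = ci[2L],
               score = log(or) / se_log, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  informative <- is.finite(tab$score) & tab$ci_low > 1
  if (!any(informative)) {
    return(list(chosen = candidates[1L], degenerate = TRUE, table = tab))
  }
  best <- which.max(ifelse(informative, tab$score, -Inf))
  list(chosen = tab$rare_max[best], degenerate = FALSE, table = tab)
}
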