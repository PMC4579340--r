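# Shared internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so seeded operations do not perturb the
#' caller's random stream. A `NULL` seed evaluates `code` unseeded.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-operation substream seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483629 + 1)
}

#' Express a count as a percentage of a total
#'
#' @param count Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places to round to (default 1, matching how turnover
#'   fractions are conventionally reported).
#' @return Numeric percentage.
#' @examples
#' format_percent(14400, 76445) # 18.8
#' @export
format_percent <- function(count, total, digits = 1) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round(100 * count / total, digits)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# Open a text connection, transparently handling gzip by file extension.
open_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Jaccard index of two character sets; NaN when both are empty.
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(NaN)
  length(intersect(a, b)) / length(u)
}

# Put two GRanges on a shared seqlevels set so overlap operations work
# even when their chromosome sets are disjoint.
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# countOverlaps for interval data.frames, robust to disjoint chromosomes.
overlap_counts <- function(query_df, subject_df, minoverlap = 1L) {
  gq <- intervals_to_granges(query_df, use_strand = FALSE)
  gs <- intervals_to_granges(subject_df, use_strand = FALSE)
  h <- harmonize_seqlevels(gq, gs)
  GenomicRanges::countOverlaps(h[[1L]], h[[2L]], minoverlap = minoverlap)
}

# Convert a 0-based half-open interval data.frame to GRanges.
intervals_to_granges <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' The single conversion point for external sources that use 1-based
#' inclusive coordinates (e.g. VCF positions, GFF intervals).
#'
#' @param start,end 1-based inclusive start and end.
#' @return A list with 0-based half-open `start` and `end`.
#' @export
to_zero_based <- function(start, end = start) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}
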