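# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# -- alignment-status rows ------------------------------------------------

status_row <- function(promoter_id, target_species, source, status,
                       target = NULL, fraction = NULL) {
  aligned <- status == "ALIGNED"
  data.frame(
    promoter_id = promoter_id, target_species = target_species,
    source = source, status = status,
    target_chrom = if (aligned) target$chrom else NA_character_,
    target_start = if (aligned) target$start else NA_integer_,
    target_end = if (aligned) target$end else NA_integer_,
    target_strand = if (aligned) target$strand else NA_character_,
    aligned_fraction = fraction %||%
      (if (aligned) 0.9 else if (status == "GAPPED") 0.02 else 0),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

dual_status <- function(promoter_id, target_species, msa, pairwise,
                        target = NULL, msa_fraction = NULL,
                        pw_fraction = NULL) {
  rbind(
    status_row(promoter_id, target_species, "msa", msa, target,
               msa_fraction),
    status_row(promoter_id, target_species, "pairwise", pairwise, target,
               pw_fraction)
  )
}

target_iv <- function(chrom = "chr1", start = 100L, end = 300L,
                      strand = "+") {
  list(chrom = chrom, start = start, end = end, strand = strand)
}

# -- expression fixtures --------------------------------------------------

tiny_sheet <- function(species = "human", tissues = c("tA", "tB"),
                       nrep = 2L,
                       categories = rep("other", length(tissues))) {
  data.frame(
    sample_id = paste(species, rep(tissues, each = nrep),
                      paste0("r", seq_len(nrep)), sep = "."),
    species = species,
    tissue_type = rep(tissues, each = nrep),
    replicate_group = paste(species, rep(tissues, each = nrep), sep = "."),
    tissue_category = rep(categories, each = nrep),
    stringsAsFactors = FALSE
  )
}

# -- independent oracles --------------------------------------------------

# Median-of-ratios size factors, written independently of the package
# (explicit loops, ratio-space median).
oracle_size_factors <- function(mat) {
  geo <- apply(mat, 1, function(row) prod(row)^(1 / length(row)))
  ok <- geo > 0
  sf <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    sf[j] <- median(mat[ok, j] / geo[ok])
  }
  sf
}

# Two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins, using lchoose arithmetic (independent of dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  probs <- vapply(lo:hi, function(x) exp(logp(x)), numeric(1))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive k-mer PWM match p-value: P(score >= s) over all 4^w words.
oracle_pwm_pvalue <- function(kmer_score, lo, background) {
  w <- ncol(lo)
  bases <- rownames(lo)
  grid <- expand.grid(rep(list(seq_len(4)), w))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    sc <- sum(lo[cbind(idx, seq_len(w))])
    if (sc >= kmer_score - 1e-12) {
      total <- total + prod(background[bases[idx]])
    }
  }
  total
}

# A small noise-free simulation shared by several tests.
noise_free_config <- function(seed = 101L, n = 200L, ...) {
  sim_config(seed = seed, n_ancestral_promoters = n,
             genome_length = 2e6,
             insertion_rate_per_lineage = 20,
             deletion_rate_per_lineage = 15,
             conflict_prob = 0, multi_prob = 0, outgroup_loss_prob = 0,
             expression_noise_sd = 0, n_variants = 0L, ...)
}
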