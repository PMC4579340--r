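# Permutation nulls, repeat coverage enrichment, score-track profiles and
# bootstrap machinery.

test_that("permuted placements are uniform over valid start positions", {
  allowed <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  iv <- data.frame(chrom = "chr1", start = 0L, end = 100L, name = "x")
  perms <- permute_intervals(iv, allowed, n_permutations = 10000L,
                             seed = 13L)
  expect_equal(unique(perms$end - perms$start), 100L)
  expect_true(all(perms$start >= 0 & perms$end <= 1000))
  # chi-square goodness of fit against the uniform over [0, 900]
  bins <- cut(perms$start, breaks = seq(0, 901, by = 100.99),
              include.lowest = TRUE)
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.001)
})

test_that("permutation preserves lengths and respects the blacklist", {
  mappable <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  blacklist <- data.frame(chrom = "chr1", start = 4000L, end = 6000L)
  allowed <- allowed_regions(mappable, blacklist)
  set.seed(2)
  iv <- data.frame(chrom = "chr1",
                   start = c(0L, 100L, 700L),
                   end = c(50L, 400L, 1500L),
                   name = c("a", "b", "c"))
  perms <- permute_intervals(iv, allowed, n_permutations = 200L, seed = 3L)
  # lengths multiset preserved within every permutation
  for (p in unique(perms$perm)[1:5]) {
    lens <- sort(perms$end[perms$perm == p] - perms$start[perms$perm == p])
    expect_equal(lens, sort(iv$end - iv$start))
  }
  # zero permuted bases fall in the blacklist
  expect_true(all(perms$end <= 4000 | perms$start >= 6000))
  # an interval longer than every allowed region errors by name
  big <- data.frame(chrom = "chr1", start = 0L, end = 9000L, name = "big")
  expect_error(permute_intervals(big, allowed, 10L), "big")
})

test_that("per-chromosome permutation keeps intervals on their chromosome", {
  allowed <- data.frame(chrom = c("chr1", "chr2"), start = 0L,
                        end = c(5000L, 5000L))
  iv <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 0L),
                   end = c(100L, 100L), name = c("a", "b"))
  perms <- permute_intervals(iv, allowed, n_permutations = 50L, seed = 5L,
                             per_chromosome = TRUE)
  expect_true(all(perms$chrom[perms$name == "a"] == "chr1"))
  expect_true(all(perms$chrom[perms$name == "b"] == "chr2"))
})

test_that("score profiles equal brute-force per-base averaging", {
  set.seed(8)
  L <- 60000L
  # a track of irregular blocks covering most of the chromosome
  edges <- sort(sample(seq(0, L, by = 10), 400))
  track <- data.frame(chrom = "chr1", start = head(edges, -1),
                      end = tail(edges, -1),
                      score = rnorm(length(edges) - 1))
  track <- track[track$start < track$end, ]
  anchors <- data.frame(chrom = "chr1",
                        start = sample(2000:50000, 20),
                        end = 0L, strand = sample(c("+", "-"), 20,
                                                  replace = TRUE))
  anchors$end <- anchors$start + sample(100:300, 20)
  cfg <- profile_config(flank = 500L, window = 50L)
  prof <- score_profile(anchors, track, cfg)

  # brute force: expand the whole track, average per window per anchor
  vec <- rep(NA_real_, L)
  for (r in seq_len(nrow(track))) {
    vec[(track$start[r] + 1):track$end[r]] <- track$score[r]
  }
  offs <- seq(-cfg$flank, cfg$flank - 1L)
  expected <- matrix(NA_real_, 20, 2 * cfg$flank %/% cfg$window)
  for (i in seq_len(20)) {
    a <- if (anchors$strand[i] == "-") anchors$end[i] - 1L else
      anchors$start[i]
    g <- if (anchors$strand[i] == "-") a - offs else a + offs
    vals <- vec[g + 1L]
    for (w in seq_len(ncol(expected))) {
      chunk <- vals[((w - 1) * cfg$window + 1):(w * cfg$window)]
      expected[i, w] <- if (all(is.na(chunk))) NA else
        mean(chunk, na.rm = TRUE)
    }
  }
  expect_equal(prof$observed, colMeans(expected, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("constant tracks give flat profiles and minus-strand mirrors plus", {
  track <- data.frame(chrom = "chr1", start = 0L, end = 50000L,
                      score = 3.25)
  anchor <- data.frame(chrom = "chr1", start = 20000L, end = 20200L,
                       strand = "+")
  cfg <- profile_config(flank = 500L)
  prof <- score_profile(anchor, track, cfg)
  expect_true(all(prof$observed == 3.25))

  # asymmetric track: minus-strand profile is the reverse of plus-strand
  track2 <- data.frame(chrom = "chr1",
                       start = seq(0L, 49000L, by = 1000L),
                       end = seq(1000L, 50000L, by = 1000L),
                       score = seq_len(50))
  # a minus-strand anchor at base a covers bases a+flank..a-flank+1, the
  # mirror image of a plus-strand anchor at base a+1
  plus_anchor <- data.frame(chrom = "chr1", start = 20001L, end = 20200L,
                            strand = "+")
  plus <- score_profile(plus_anchor, track2, cfg)$observed
  minus_anchor <- data.frame(chrom = "chr1", start = 19801L,
                             end = 20001L, strand = "-")
  minus <- score_profile(minus_anchor, track2, cfg)$observed
  expect_equal(minus, rev(plus), tolerance = 1e-12)
})

test_that("profiles are invariant to anchor order", {
  set.seed(12)
  track <- data.frame(chrom = "chr1", start = seq(0L, 19800L, 200L),
                      end = seq(200L, 20000L, 200L), score = rnorm(100))
  anchors <- data.frame(chrom = "chr1", start = sample(3000:15000, 10),
                        end = 0L, strand = "+")
  anchors$end <- anchors$start + 150L
  p1 <- score_profile(anchors, track, profile_config(flank = 200L))
  p2 <- score_profile(anchors[sample(10), ], track,
                      profile_config(flank = 200L))
  expect_equal(p1$observed, p2$observed)
})

test_that("repeat coverage fold is exact for fully covered promoters", {
  # promoters completely covered by repeats; background coverage 0.2
  prom <- data.frame(chrom = "chr1",
                     start = seq(10000L, 19000L, by = 1000L),
                     end = seq(10200L, 19200L, by = 1000L),
                     strand = "+")
  reps <- data.frame(chrom = "chr1", start = prom$start - 1500L,
                     end = prom$end + 1500L, family = "LTR")
  bg <- data.frame(chrom = "chr1",
                   start = seq(30000L, 39000L, by = 1000L),
                   end = seq(30200L, 39200L, by = 1000L), strand = "+")
  # cover exactly 10 bp of every 50 bp around the background anchors
  bg_steps <- seq(28000L, 41000L, by = 50L)
  bg_reps <- data.frame(chrom = "chr1", start = bg_steps,
                        end = bg_steps + 10L, family = "SINE")
  enr <- repeat_enrichment(prom, rbind(reps, bg_reps),
                           background = "conserved_promoters",
                           background_set = bg,
                           config = profile_config(flank = 1000L),
                           seed = 4L)
  # over the promoter body (offset 0) coverage is 1 vs 0.2
  body <- enr$windows[enr$windows$offset == 0, ]
  expect_equal(body$observed, 1)
  expect_equal(body$fold, 1 / 0.2, tolerance = 1e-12)
  expect_equal(enr$family_frequency$frequency[
    enr$family_frequency$family == "LTR"], 1)
  # no repeats anywhere: zero folds, empty family table
  enr0 <- repeat_enrichment(prom, reps[0, ],
                            background = "conserved_promoters",
                            background_set = bg, seed = 4L)
  expect_true(all(enr0$windows$fold == 0))
  expect_equal(nrow(enr0$family_frequency), 0L)
  expect_error(repeat_enrichment(prom[0, ], reps,
                                 background = "conserved_promoters",
                                 background_set = bg), "empty")
})

test_that("uniformly placed features sit inside their own permutation null", {
  # features scattered uniformly over the allowed regions should show no
  # enrichment: the observed overlap statistic falls inside the null band
  covered <- 0L
  n_runs <- 30L
  allowed <- data.frame(chrom = "chr1", start = 0L, end = 200000L)
  annotation <- data.frame(chrom = "chr1",
                           start = seq(0L, 199000L, by = 1000L))
  annotation$end <- annotation$start + 200L
  for (s in seq_len(n_runs)) {
    feats <- with_seed(800 + s, {
      st <- sample.int(199900L, 150L) - 1L
      data.frame(chrom = "chr1", start = st, end = st + 100L)
    })
    obs <- mean(overlap_counts(feats, annotation) > 0)
    perms <- permute_intervals(feats, allowed, n_permutations = 100L,
                               seed = 900 + s)
    hit <- overlap_counts(perms, annotation) > 0
    null <- tapply(hit, perms$perm, mean)
    band <- quantile(null, c(0.025, 0.975))
    if (obs >= band[1] && obs <= band[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_runs, 0.9)
})

test_that("bootstrap proportions are seeded and cover the truth", {
  flags <- rep(c(TRUE, FALSE), c(30, 70))
  b1 <- bootstrap_proportion(flags, n_boot = 500L, seed = 1L)
  b2 <- bootstrap_proportion(flags, n_boot = 500L, seed = 1L)
  expect_equal(b1, b2)
  expect_equal(b1$proportion, 0.3)
  # degenerate inputs give zero-width intervals
  b3 <- bootstrap_proportion(rep(TRUE, 10), seed = 2L)
  expect_equal(c(b3$ci_low, b3$ci_high), c(1, 1))
  b4 <- bootstrap_proportion(FALSE, seed = 3L)
  expect_equal(c(b4$proportion, b4$ci_low, b4$ci_high), c(0, 0, 0))
  # coverage of the true proportion across seeded replicates
  covered <- 0L
  for (s in 1:50) {
    f <- with_seed(100 + s, runif(1000) < 0.3)
    b <- bootstrap_proportion(f, n_boot = 400L, seed = 200 + s)
    if (b$ci_low <= 0.3 && b$ci_high >= 0.3) covered <- covered + 1L
  }
  expect_gte(covered, 45L)
})
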