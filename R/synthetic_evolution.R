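# Two-lineage promoter evolution simulator with ground-truth labels.
#
# The simulator works at the interval level (no nucleotide sequence): an
# ancestral genome carries promoters; two focal lineages evolve through
# whole-segment insertions (optionally repeat-derived) and whole-promoter
# deletions; aligned promoters can lose or diminish expression in one
# lineage. Four outgroups retain ancestral sequence with an independent
# per-outgroup loss probability. Every downstream input table/format is
# emitted together with one TrueHistory label per promoter.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package's tests assume: two
#' focal lineages with equal insertion rates, a 3.5x deletion-rate excess on
#' the second ("mouse-like") lineage, a 52-tissue matched expression panel
#' with three replicates, a 0.3 per-outgroup ancestral-loss probability,
#' and repeat-derived insertions at a 0.6 fraction against a 0.2 genomic
#' background coverage.
#'
#' @param seed Master seed; fully determines the dataset.
#' @param genome_length Bases per chromosome.
#' @param n_chromosomes Chromosome count (one pseudo-chromosome by
#'   default).
#' @param n_ancestral_promoters Promoters in the common ancestor.
#' @param insertion_rate_per_lineage Expected de novo promoter insertions
#'   per lineage (Poisson mean).
#' @param deletion_rate_per_lineage Expected promoter deletions per lineage
#'   (Poisson mean; multiplied by `mouse_deletion_multiplier` on lineage B).
#' @param mouse_deletion_multiplier Deletion-rate factor for the second
#'   focal lineage.
#' @param repeat_insertion_fraction Probability an inserted segment is
#'   repeat-derived.
#' @param repeat_family_weights Named sampling weights over repeat families
#'   for repeat-derived insertions (must sum to 1).
#' @param repeat_background_fraction Genome-wide repeat coverage fraction.
#' @param n_tissue_types Matched tissue panel size (default 52).
#' @param n_replicates_per_sample Biological replicates per sample.
#' @param expression_noise_sd Replicate noise s.d. on the log scale.
#' @param frac_tissue_restricted Fraction of promoters with restricted
#'   (1-3 tissue) expression architecture.
#' @param expr_turnover_prob Probability an aligned promoter loses all
#'   activity in one lineage.
#' @param diminish_prob Probability of strong expression reduction in one
#'   lineage.
#' @param diminish_factor Multiplicative expression reduction for
#'   diminished promoters.
#' @param outgroup_loss_prob Independent per-outgroup probability that
#'   ancestral sequence is unalignable in that outgroup.
#' @param conflict_prob Probability that the two alignment sources disagree
#'   for a promoter's opposing-species projection.
#' @param multi_prob Probability of a multi-locus projection in one source.
#' @param selection_regimes Named map region-class -> regime for variant
#'   simulation (classes `promoter`, `background`; regimes `neutral`,
#'   `purifying`, `positive`).
#' @param n_variants Number of simulated variant sites.
#' @param n_sample_chromosomes Sampled chromosome count for the allele
#'   frequency spectrum.
#' @param blacklist_fraction,unmappable_fraction Fractions of the genome
#'   masked.
#' @param species Names of the two focal species.
#' @param outgroup_species Names of the four outgroups.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 4e6,
                       n_chromosomes = 1L,
                       n_ancestral_promoters = 500L,
                       insertion_rate_per_lineage = 50,
                       deletion_rate_per_lineage = 50,
                       mouse_deletion_multiplier = 3.5,
                       repeat_insertion_fraction = 0.6,
                       repeat_family_weights = c(LTR = 0.35, SINE = 0.30,
                                                 LINE = 0.25,
                                                 low_complexity = 0.10,
                                                 none = 0),
                       repeat_background_fraction = 0.2,
                       n_tissue_types = 52L,
                       n_replicates_per_sample = 3L,
                       expression_noise_sd = 0.2,
                       frac_tissue_restricted = 0.4,
                       expr_turnover_prob = 0.05,
                       diminish_prob = 0.03,
                       diminish_factor = 0.02,
                       outgroup_loss_prob = 0.3,
                       conflict_prob = 0.02,
                       multi_prob = 0.01,
                       selection_regimes = c(promoter = "purifying",
                                             background = "neutral"),
                       n_variants = 20000L,
                       n_sample_chromosomes = 2000L,
                       blacklist_fraction = 0.05,
                       unmappable_fraction = 0.1,
                       species = c("human", "mouse"),
                       outgroup_species = c("dog", "horse", "cow", "pig")) {
  assert_nonneg(insertion_rate_per_lineage, "insertion_rate_per_lineage")
  assert_nonneg(deletion_rate_per_lineage, "deletion_rate_per_lineage")
  assert_nonneg(mouse_deletion_multiplier, "mouse_deletion_multiplier")
  for (nm in c("repeat_insertion_fraction", "repeat_background_fraction",
               "frac_tissue_restricted", "expr_turnover_prob",
               "diminish_prob", "outgroup_loss_prob", "conflict_prob",
               "multi_prob", "blacklist_fraction", "unmappable_fraction")) {
    assert_prob(get(nm), nm)
  }
  if (abs(sum(repeat_family_weights) - 1) > 1e-8) {
    stop("repeat_family_weights must sum to 1", call. = FALSE)
  }
  if (!all(selection_regimes %in% c("neutral", "purifying", "positive"))) {
    stop("unknown selection regime", call. = FALSE)
  }
  stopifnot(length(species) == 2L, n_tissue_types >= 1L,
            n_replicates_per_sample >= 1L, genome_length > 0,
            n_chromosomes >= 1L)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  genome: %d x %.2g bp; %d ancestral promoters\n",
              x$n_chromosomes, x$genome_length, x$n_ancestral_promoters))
  cat(sprintf("  rates: ins %.3g / del %.3g per lineage (x%.2g on %s)\n",
              x$insertion_rate_per_lineage, x$deletion_rate_per_lineage,
              x$mouse_deletion_multiplier, x$species[2L]))
  cat(sprintf("  expression: %d tissues x %d reps, noise sd %.2g\n",
              x$n_tissue_types, x$n_replicates_per_sample,
              x$expression_noise_sd))
  invisible(x)
}

# Tissue panel with testis/immunity/brain category labels.
tissue_panel <- function(n_tissues) {
  tt <- sprintf("tissue%02d", seq_len(n_tissues))
  cat <- rep("other", n_tissues)
  if (n_tissues >= 1L) cat[1L] <- "testis"
  if (n_tissues >= 6L) cat[2:6] <- "immunity"
  if (n_tissues >= 14L) cat[7:14] <- "brain"
  data.frame(tissue_type = tt, tissue_category = cat,
             stringsAsFactors = FALSE)
}

# Allele-frequency spectrum weights over derived counts 1..n-1.
sfs_weights <- function(regime, n_chrom) {
  j <- seq_len(n_chrom - 1L)
  switch(regime,
         neutral = 1 / j,
         purifying = exp(-0.01 * j) / j,
         positive = 1 / (n_chrom - j),
         stop("unknown selection regime: ", regime, call. = FALSE))
}

#' Simulate derived allele frequencies under a selection regime
#'
#' Sites draw a derived-allele count j from a spectrum over 1..n-1 sampled
#' chromosomes: proportional to 1/j under neutrality, down-weighted
#' exponentially in j under purifying selection (an excess of rare derived
#' alleles), and mirrored (1/(n-j)) under positive selection (an excess of
#' high-frequency derived alleles). Reference/alternate labelling and the
#' reported alternate frequency are scrambled against the ancestral state
#' so that polarization is non-trivial.
#'
#' @param regime "neutral", "purifying" or "positive".
#' @param n_sites Number of variant sites (0 gives an empty table).
#' @param seed Integer seed (optional).
#' @param n_chrom Sampled chromosome count (spectrum resolution).
#' @param chrom Chromosome name for the emitted table.
#' @return Variant data.frame (chrom, pos, ref, alt, ancestral,
#'   alt_frequency, unresolved).
#' @export
simulate_allele_frequencies <- function(regime, n_sites, seed = NULL,
                                        n_chrom = 2000L, chrom = "chr1") {
  stopifnot(n_sites >= 0)
  if (!regime %in% c("neutral", "purifying", "positive")) {
    stop("unknown selection regime: ", regime, call. = FALSE)
  }
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ancestral = character(), alt_frequency = numeric(),
                      unresolved = logical(), stringsAsFactors = FALSE)
  if (n_sites == 0L) return(empty)
  with_seed(seed, {
    w <- sfs_weights(regime, n_chrom)
    j <- sample.int(n_chrom - 1L, n_sites, replace = TRUE, prob = w)
    daf <- j / n_chrom
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, n_sites, replace = TRUE)
    der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    flip <- stats::runif(n_sites) < 0.5
    ref <- ifelse(flip, der, anc)
    alt <- ifelse(flip, anc, der)
    af <- ifelse(flip, 1 - daf, daf)
    data.frame(chrom = chrom, pos = sort(sample.int(1e8, n_sites)) - 1L,
               ref = ref, alt = alt, ancestral = anc, alt_frequency = af,
               unresolved = FALSE, stringsAsFactors = FALSE)
  })
}

#' Expected rare/nonrare reference counts under a frequency spectrum
#'
#' @param total Total reference variant count to apportion.
#' @param regime Spectrum regime (default "neutral").
#' @param n_chrom Sampled chromosome count.
#' @param config A [daf_config()].
#' @return Integer vector `(rare, nonrare)`.
#' @export
expected_reference_counts <- function(total = 2e6, regime = "neutral",
                                      n_chrom = 2000L,
                                      config = daf_config()) {
  w <- sfs_weights(regime, n_chrom)
  daf <- seq_len(n_chrom - 1L) / n_chrom
  p_rare <- sum(w[daf < config$rare_max]) / sum(w)
  p_nonrare <- sum(w[daf > config$nonrare_min]) / sum(w)
  c(rare = round(total * p_rare), nonrare = round(total * p_nonrare))
}

# Event labels for a config's species pair.
sim_event_levels <- function(species) {
  c("ancestral_conserved",
    paste0("inserted_in_", species),
    paste0("deleted_from_", species),
    paste0("expression_lost_in_", species),
    paste0("diminished_in_", species))
}

#' Simulate a two-lineage promoter evolution dataset
#'
#' Evolves an ancestral promoter complement down two focal lineages plus
#' four outgroups and emits every pipeline input: promoter BED records with
#' class/gene annotation, dual-source alignment-status tables against the
#' opposing species and outgroups, replicate-level expression matrices with
#' sample sheets, repeat annotations with family labels, a conservation
#' score track, masks, a variant table, ortholog and gene-map tables, and
#' the per-promoter ground-truth history.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  sp <- cfg$species
  flank <- 1000L
  slot_w <- 3000L
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  slots_per_chrom <- floor(cfg$genome_length / slot_w)
  slot_chrom <- rep(chroms, each = slots_per_chrom)
  slot_start <- rep((seq_len(slots_per_chrom) - 1L) * slot_w,
                    cfg$n_chromosomes)
  n_slots <- length(slot_chrom)

  n_anc <- cfg$n_ancestral_promoters
  n_ins <- stats::rpois(2L, cfg$insertion_rate_per_lineage)
  n_del <- c(stats::rpois(1L, cfg$deletion_rate_per_lineage),
             stats::rpois(1L, cfg$deletion_rate_per_lineage *
                            cfg$mouse_deletion_multiplier))
  if (sum(n_del) > 0.8 * n_anc) {
    stop("deletion rates too high for the ancestral promoter count",
         call. = FALSE)
  }

  n_mask <- ceiling(n_slots * (cfg$blacklist_fraction +
                                 cfg$unmappable_fraction))
  n_needed <- n_anc + sum(n_ins) + n_mask
  if (n_needed > n_slots) {
    stop("genome too small: ", n_needed, " slots needed, ", n_slots,
         " available; increase genome_length or n_chromosomes",
         call. = FALSE)
  }

  slot_perm <- sample.int(n_slots)
  take <- function(k) {
    idx <- slot_perm[seq_len(k)]
    slot_perm <<- slot_perm[-seq_len(k)]
    idx
  }
  n_black <- ceiling(n_slots * cfg$blacklist_fraction)
  n_unmap <- ceiling(n_slots * cfg$unmappable_fraction)
  black_idx <- take(n_black)
  unmap_idx <- take(n_unmap)
  anc_idx <- take(n_anc)
  insA_idx <- take(n_ins[1L])
  insB_idx <- take(n_ins[2L])

  slot_interval <- function(idx, len) {
    data.frame(chrom = slot_chrom[idx],
               start = slot_start[idx] + flank,
               end = slot_start[idx] + flank + len,
               stringsAsFactors = FALSE)
  }

  blacklist <- data.frame(chrom = slot_chrom[black_idx],
                          start = slot_start[black_idx],
                          end = slot_start[black_idx] + slot_w,
                          stringsAsFactors = FALSE)
  unmappable <- data.frame(chrom = slot_chrom[unmap_idx],
                           start = slot_start[unmap_idx],
                           end = slot_start[unmap_idx] + slot_w,
                           stringsAsFactors = FALSE)
  # mappable = genome minus unmappable
  genome_df <- data.frame(chrom = chroms, start = 0L,
                          end = as.integer(cfg$genome_length),
                          stringsAsFactors = FALSE)
  gm <- GenomicRanges::setdiff(
    intervals_to_granges(genome_df, use_strand = FALSE),
    GenomicRanges::reduce(intervals_to_granges(unmappable,
                                               use_strand = FALSE))
  )
  mappable <- data.frame(chrom = as.character(GenomicRanges::seqnames(gm)),
                         start = GenomicRanges::start(gm) - 1L,
                         end = GenomicRanges::end(gm),
                         stringsAsFactors = FALSE)

  # --- ancestral promoters and their lineage histories ------------------
  anc_len <- sample(100:400, n_anc, replace = TRUE)
  anc_iv <- slot_interval(anc_idx, anc_len)
  anc_strand <- sample(c("+", "-"), n_anc, replace = TRUE)
  anc_class <- sample(c("coding", "noncoding", "anonymous"), n_anc,
                      replace = TRUE, prob = c(0.55, 0.25, 0.20))

  event <- rep("ancestral_conserved", n_anc)
  del_pick <- sample.int(n_anc, sum(n_del))
  if (n_del[1L] > 0L) {
    event[del_pick[seq_len(n_del[1L])]] <- paste0("deleted_from_", sp[1L])
  }
  if (n_del[2L] > 0L) {
    event[del_pick[n_del[1L] + seq_len(n_del[2L])]] <-
      paste0("deleted_from_", sp[2L])
  }
  conserved <- which(event == "ancestral_conserved")
  u <- stats::runif(length(conserved))
  lost <- conserved[u < cfg$expr_turnover_prob]
  dim_pick <- conserved[u >= cfg$expr_turnover_prob &
                          u < cfg$expr_turnover_prob + cfg$diminish_prob]
  lost_lineage <- sample(sp, length(lost), replace = TRUE)
  event[lost] <- paste0("expression_lost_in_", lost_lineage)
  dim_lineage <- sample(sp, length(dim_pick), replace = TRUE)
  event[dim_pick] <- paste0("diminished_in_", dim_lineage)

  # per-outgroup ancestral presence (shared by both focal species' views)
  og <- cfg$outgroup_species
  og_present <- matrix(stats::runif(n_anc * length(og)) >=
                         cfg$outgroup_loss_prob, n_anc, length(og),
                       dimnames = list(NULL, og))
  # deletions need >= 1 retaining outgroup to be resolvable as deletions
  del_rows <- grep("^deleted_from_", event)
  for (i in del_rows) {
    if (!any(og_present[i, ])) {
      og_present[i, sample.int(length(og), 1L)] <- TRUE
    }
  }

  # --- inserted promoters ----------------------------------------------
  ins_len <- lapply(n_ins, function(k) sample(100:400, k, replace = TRUE))
  ins_iv <- list(slot_interval(insA_idx, ins_len[[1L]]),
                 slot_interval(insB_idx, ins_len[[2L]]))
  fam_pool <- cfg$repeat_family_weights
  draw_provenance <- function(k) {
    prov <- rep("none", k)
    is_rep <- stats::runif(k) < cfg$repeat_insertion_fraction
    fams <- fam_pool[names(fam_pool) != "none"]
    if (any(is_rep) && sum(fams) > 0) {
      prov[is_rep] <- sample(names(fams), sum(is_rep), replace = TRUE,
                             prob = fams)
    }
    prov
  }
  ins_prov <- lapply(n_ins, draw_provenance)

  # --- assemble per-species promoter tables ----------------------------
  n_genes <- max(1L, round(n_anc / 3))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  anc_gene <- ifelse(stats::runif(n_anc) < 0.75,
                     sample(gene_ids, n_anc, replace = TRUE),
                     NA_character_)
  orthologs <- data.frame(gene_id_a = paste0(sp[1L], ".", gene_ids),
                          gene_id_b = paste0(sp[2L], ".", gene_ids),
                          stringsAsFactors = FALSE)

  truth <- data.frame(
    ancestral_id = c(sprintf("anc%05d", seq_len(n_anc)),
                     sprintf("ins_%s_%04d", sp[1L], seq_len(n_ins[1L])),
                     sprintf("ins_%s_%04d", sp[2L], seq_len(n_ins[2L]))),
    event = c(event,
              rep(paste0("inserted_in_", sp[1L]), n_ins[1L]),
              rep(paste0("inserted_in_", sp[2L]), n_ins[2L])),
    repeat_provenance = c(rep("none", n_anc), ins_prov[[1L]],
                          ins_prov[[2L]]),
    stringsAsFactors = FALSE
  )

  # a species carries a promoter RECORD only where it has activity ...
  present_in <- function(which_sp) {
    c(!(event %in% c(paste0("deleted_from_", which_sp),
                     paste0("expression_lost_in_", which_sp))),
      rep(which_sp == sp[1L], n_ins[1L]),
      rep(which_sp == sp[2L], n_ins[2L]))
  }
  # ... but its SEQUENCE is alignable wherever it was not deleted
  # (expression loss leaves the orthologous sequence in place)
  seq_present_in <- function(which_sp) {
    c(event != paste0("deleted_from_", which_sp),
      rep(which_sp == sp[1L], n_ins[1L]),
      rep(which_sp == sp[2L], n_ins[2L]))
  }
  all_iv <- rbind(anc_iv, ins_iv[[1L]], ins_iv[[2L]])
  all_strand <- c(anc_strand,
                  sample(c("+", "-"), n_ins[1L], replace = TRUE),
                  sample(c("+", "-"), n_ins[2L], replace = TRUE))
  all_class <- c(anc_class,
                 sample(c("coding", "noncoding", "anonymous"), n_ins[1L],
                        replace = TRUE, prob = c(0.55, 0.25, 0.20)),
                 sample(c("coding", "noncoding", "anonymous"), n_ins[2L],
                        replace = TRUE, prob = c(0.55, 0.25, 0.20)))
  ins_gene <- function(k) ifelse(stats::runif(k) < 0.5,
                                 sample(gene_ids, k, replace = TRUE),
                                 NA_character_)
  all_gene <- c(anc_gene, ins_gene(n_ins[1L]), ins_gene(n_ins[2L]))

  promoters <- list()
  id_of <- list()
  for (si in 1:2) {
    keep <- which(present_in(sp[si]))
    ids <- sprintf("%s_p%05d", sp[si], seq_along(keep))
    id_map <- rep(NA_character_, nrow(all_iv))
    id_map[keep] <- ids
    id_of[[sp[si]]] <- id_map
    promoters[[sp[si]]] <- data.frame(
      promoter_id = ids,
      chrom = all_iv$chrom[keep],
      start = all_iv$start[keep],
      end = all_iv$end[keep],
      strand = all_strand[keep],
      species = sp[si],
      promoter_class = all_class[keep],
      gene_id = ifelse(is.na(all_gene[keep]), NA_character_,
                       paste0(sp[si], ".", all_gene[keep])),
      truth_row = keep,
      stringsAsFactors = FALSE
    )
  }

  # --- alignment status tables -----------------------------------------
  n_all <- nrow(all_iv)
  is_inserted <- c(rep(FALSE, n_anc), rep(TRUE, n_ins[1L] + n_ins[2L]))
  og_present_all <- rbind(og_present,
                          matrix(FALSE, n_ins[1L] + n_ins[2L], length(og),
                                 dimnames = list(NULL, og)))

  status <- list()
  for (si in 1:2) {
    me <- sp[si]
    other <- sp[3L - si]
    pr <- promoters[[me]]
    rows_out <- list()
    # opposing sequence presence of each of my promoters
    opp_present <- seq_present_in(other)[pr$truth_row]
    noise_ok <- !is_inserted[pr$truth_row]
    conflict <- noise_ok & stats::runif(nrow(pr)) < cfg$conflict_prob
    multi <- noise_ok & !conflict & stats::runif(nrow(pr)) < cfg$multi_prob
    targets <- c(other, og)
    present_mat <- cbind(opp_present, og_present_all[pr$truth_row, ,
                                                     drop = FALSE])
    colnames(present_mat) <- targets
    for (ti in seq_along(targets)) {
      tgt <- targets[ti]
      pres <- present_mat[, ti]
      for (src in c("msa", "pairwise")) {
        eff <- pres
        st_multi <- rep(FALSE, nrow(pr))
        if (tgt == other) {
          if (src == "pairwise") eff <- ifelse(conflict, !pres, pres)
          if (src == "msa") st_multi <- multi
        }
        st <- ifelse(st_multi, "MULTI",
                     ifelse(eff, "ALIGNED",
                            sample(c("GAPPED", "UNMAPPED"), nrow(pr),
                                   replace = TRUE)))
        frac <- ifelse(st == "ALIGNED", stats::runif(nrow(pr), 0.7, 1.0),
                       ifelse(st == "GAPPED",
                              stats::runif(nrow(pr), 0, 0.3), 0))
        aligned <- st == "ALIGNED"
        rows_out[[length(rows_out) + 1L]] <- data.frame(
          promoter_id = pr$promoter_id,
          target_species = tgt,
          source = src,
          status = st,
          target_chrom = ifelse(aligned, pr$chrom, NA_character_),
          target_start = ifelse(aligned, pr$start, NA_integer_),
          target_end = ifelse(aligned, pr$end, NA_integer_),
          target_strand = ifelse(aligned, pr$strand, NA_character_),
          aligned_fraction = round(frac, 4L),
          stringsAsFactors = FALSE
        )
      }
    }
    status[[me]] <- do.call(rbind, rows_out)
  }

  # --- expression ------------------------------------------------------
  panel <- tissue_panel(cfg$n_tissue_types)
  nt <- nrow(panel)
  restricted <- stats::runif(n_all) < cfg$frac_tissue_restricted
  base_means <- matrix(0, n_all, nt)
  broad_rows <- which(!restricted)
  base_means[broad_rows, ] <- matrix(
    stats::rlnorm(length(broad_rows) * nt, meanlog = log(5), sdlog = 1),
    length(broad_rows), nt
  )
  for (i in which(restricted)) {
    k <- sample(1:3, 1L)
    base_means[i, sample.int(nt, k)] <- stats::rlnorm(k, log(8), 0.5)
  }

  expression <- list()
  for (si in 1:2) {
    me <- sp[si]
    pr <- promoters[[me]]
    means <- base_means[pr$truth_row, , drop = FALSE]
    dim_here <- grepl(paste0("^diminished_in_", me),
                      truth$event[pr$truth_row])
    means[dim_here, ] <- means[dim_here, ] * cfg$diminish_factor
    nrep <- cfg$n_replicates_per_sample
    sheet <- data.frame(
      sample_id = paste(me, rep(panel$tissue_type, each = nrep),
                        paste0("rep", seq_len(nrep)), sep = "."),
      species = me,
      tissue_type = rep(panel$tissue_type, each = nrep),
      replicate_group = paste(me, rep(panel$tissue_type, each = nrep),
                              sep = "."),
      tissue_category = rep(panel$tissue_category, each = nrep),
      stringsAsFactors = FALSE
    )
    depth <- exp(stats::rnorm(nrow(sheet), 0, 0.15))
    mat <- matrix(0, nrow(pr), nrow(sheet),
                  dimnames = list(pr$promoter_id, sheet$sample_id))
    tissue_col <- match(sheet$tissue_type, panel$tissue_type)
    for (j in seq_len(nrow(sheet))) {
      noise <- exp(stats::rnorm(nrow(pr), 0, cfg$expression_noise_sd))
      mat[, j] <- means[, tissue_col[j]] * noise * depth[j]
    }
    expression[[me]] <- list(matrix = mat, sheet = sheet)
  }

  # --- repeats ---------------------------------------------------------
  fam_names <- names(fam_pool)[names(fam_pool) != "none"]
  fam_w <- fam_pool[fam_names]
  if (sum(fam_w) == 0) fam_w[] <- 1
  background_repeats <- function() {
    target <- cfg$repeat_background_fraction * cfg$genome_length *
      cfg$n_chromosomes
    lens <- integer(0)
    while (sum(lens) < target) {
      lens <- c(lens, sample(300:3000, 200, replace = TRUE))
    }
    lens <- lens[cumsum(lens) <= target]
    cc <- sample(chroms, length(lens), replace = TRUE)
    st <- floor(stats::runif(length(lens)) *
                  (cfg$genome_length - lens))
    data.frame(chrom = cc, start = as.integer(st),
               end = as.integer(st + lens),
               family = sample(fam_names, length(lens), replace = TRUE,
                               prob = fam_w),
               stringsAsFactors = FALSE)
  }
  repeats <- list()
  for (si in 1:2) {
    me <- sp[si]
    rep_bg <- background_repeats()
    pr <- promoters[[me]]
    prov <- truth$repeat_provenance[pr$truth_row]
    ins_here <- grepl(paste0("^inserted_in_", me),
                      truth$event[pr$truth_row]) & prov != "none"
    if (any(ins_here)) {
      ext <- sample(0:200, sum(ins_here), replace = TRUE)
      rep_ins <- data.frame(
        chrom = pr$chrom[ins_here],
        start = pmax(0L, pr$start[ins_here] - ext),
        end = pr$end[ins_here] + sample(0:200, sum(ins_here),
                                        replace = TRUE),
        family = prov[ins_here],
        stringsAsFactors = FALSE
      )
      rep_bg <- rbind(rep_bg, rep_ins)
    }
    repeats[[me]] <- rep_bg[order(rep_bg$chrom, rep_bg$start), ]
  }

  # --- conservation track ----------------------------------------------
  conservation <- list()
  block <- 200L
  for (si in 1:2) {
    me <- sp[si]
    pr <- promoters[[me]]
    constrained <- truth$event[pr$truth_row] == "ancestral_conserved" |
      grepl("^diminished_in_", truth$event[pr$truth_row])
    rows <- list()
    for (cc in chroms) {
      n_block <- ceiling(cfg$genome_length / block)
      vec <- rep(stats::rnorm(n_block, 0, 0.3), each = block)
      vec <- vec[seq_len(cfg$genome_length)]
      sel <- which(pr$chrom == cc & constrained)
      for (i in sel) {
        vec[(pr$start[i] + 1L):pr$end[i]] <- stats::rnorm(1L, 2, 0.3)
      }
      r <- rle(vec)
      ends <- cumsum(r$lengths)
      rows[[cc]] <- data.frame(chrom = cc,
                               start = ends - r$lengths,
                               end = ends,
                               score = round(r$values, 4L),
                               stringsAsFactors = FALSE)
    }
    conservation[[me]] <- do.call(rbind, rows)
  }

  # --- variants (population data on the first focal species) -----------
  regime_of <- cfg$selection_regimes
  n_var <- cfg$n_variants
  variants <- NULL
  if (n_var > 0L) {
    pos <- sort(sample.int(cfg$genome_length, n_var, replace = FALSE)) - 1L
    vchrom <- sample(chroms, n_var, replace = TRUE)
    vg <- GenomicRanges::GRanges(vchrom, IRanges::IRanges(pos + 1L,
                                                          pos + 1L))
    pg <- intervals_to_granges(promoters[[sp[1L]]], use_strand = FALSE)
    in_prom <- GenomicRanges::countOverlaps(vg, pg) > 0L
    regime <- ifelse(in_prom, regime_of[["promoter"]],
                     regime_of[["background"]])
    variants <- data.frame(chrom = vchrom, pos = pos,
                           ref = NA_character_, alt = NA_character_,
                           ancestral = NA_character_,
                           alt_frequency = NA_real_,
                           region_class = ifelse(in_prom, "promoter",
                                                 "background"),
                           stringsAsFactors = FALSE)
    for (rg in unique(regime)) {
      idx <- which(regime == rg)
      vv <- simulate_allele_frequencies(rg, length(idx),
                                        n_chrom = cfg$n_sample_chromosomes)
      variants$ref[idx] <- vv$ref
      variants$alt[idx] <- vv$alt
      variants$ancestral[idx] <- vv$ancestral
      variants$alt_frequency[idx] <- vv$alt_frequency
    }
    # a few unresolved ancestral states and indels, to exercise filters
    n_unres <- ceiling(0.02 * n_var)
    variants$ancestral[sample.int(n_var, n_unres)] <- "."
    n_indel <- ceiling(0.02 * n_var)
    ind <- sample.int(n_var, n_indel)
    variants$ref[ind] <- paste0(variants$ref[ind], "A")
  }

  structure(list(
    config = cfg,
    promoters = promoters,
    alignment_status = status,
    expression = expression,
    repeats = repeats,
    conservation = conservation,
    variants = variants,
    mappable = mappable,
    blacklist = blacklist,
    orthologs = orthologs,
    truth = truth,
    truth_ids = id_of
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  sp <- x$config$species
  cat("Simulated two-lineage promoter dataset (seed ",
      x$config$seed, ")\n", sep = "")
  for (s in sp) {
    cat(sprintf("  %s: %d promoters, %d alignment-status rows\n", s,
                nrow(x$promoters[[s]]), nrow(x$alignment_status[[s]])))
  }
  cat("  truth events:\n")
  tab <- table(x$truth$event)
  for (nm in names(tab)) cat(sprintf("    %-28s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits BED6 promoters, gene maps, alignment-status TSVs, expression
#' matrices and sample sheets, repeat BEDs (family in column 7),
#' conservation bedGraphs, masks, the variant TSV, ortholog table and truth
#' table.
#'
#' @param ds A `sim_dataset`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sp <- ds$config$species
  paths <- character(0)
  p <- function(...) file.path(outdir, paste0(...))
  for (s in sp) {
    pr <- ds$promoters[[s]]
    write_bed(data.frame(chrom = pr$chrom, start = pr$start, end = pr$end,
                         name = pr$promoter_id, score = 0,
                         strand = pr$strand), p("promoters_", s, ".bed"))
    gm <- data.frame(promoter_id = pr$promoter_id,
                     promoter_class = pr$promoter_class,
                     gene_id = ifelse(is.na(pr$gene_id), ".", pr$gene_id))
    utils::write.table(gm, p("genemap_", s, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_alignment_status(ds$alignment_status[[s]],
                           p("status_", s, ".tsv"))
    write_expression(ds$expression[[s]]$matrix, ds$expression[[s]]$sheet,
                     p("expression_", s, ".tsv"), p("samples_", s, ".tsv"))
    rr <- ds$repeats[[s]]
    utils::write.table(
      data.frame(rr$chrom, rr$start, rr$end, ".", 0, ".", rr$family),
      p("repeats_", s, ".bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
    write_bedgraph(ds$conservation[[s]], p("conservation_", s,
                                           ".bedGraph"))
    paths <- c(paths, p("promoters_", s, ".bed"), p("genemap_", s, ".tsv"),
               p("status_", s, ".tsv"), p("expression_", s, ".tsv"),
               p("samples_", s, ".tsv"), p("repeats_", s, ".bed"),
               p("conservation_", s, ".bedGraph"))
  }
  write_bed(ds$mappable, p("mappable.bed"))
  write_bed(ds$blacklist, p("blacklist.bed"))
  if (!is.null(ds$variants)) write_variants(ds$variants, p("variants.tsv"))
  utils::write.table(ds$orthologs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth[[paste0("id_", sp[1L])]] <- ds$truth_ids[[sp[1L]]]
  truth[[paste0("id_", sp[2L])]] <- ds$truth_ids[[sp[2L]]]
  truth[is.na(truth)] <- "."
  utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p("mappable.bed"), p("blacklist.bed"),
             p("orthologs.tsv"), p("truth.tsv"),
             if (!is.null(ds$variants)) p("variants.tsv"))
  invisible(paths)
}

#' Expected classifier outcome for each truth event
#'
#' The noise-free mapping from a promoter's true history to the sequence
#' fate its record in a given species must receive.
#'
#' @param events Character vector of truth event labels.
#' @param species The species whose records are being checked.
#' @param other The opposing species.
#' @return Character vector of expected sequence fates (NA when the
#'   promoter has no record in `species`).
#' @export
expected_sequence_fate <- function(events, species, other) {
  ifelse(events == paste0("inserted_in_", species), "INSERTED",
  ifelse(events == paste0("deleted_from_", other), "DELETED_IN_OPPOSING",
  ifelse(events %in% c(paste0("inserted_in_", other),
                       paste0("deleted_from_", species),
                       paste0("expression_lost_in_", species)),
         NA_character_, "ALIGNED")))
}
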