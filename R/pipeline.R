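# End-to-end orchestration: simulate (or load) -> expression -> classify ->
# genes -> daf -> enrich -> report, with a machine-readable manifest.

#' Classify a whole dataset in both directions
#'
#' Builds expression profiles for both focal species and classifies every
#' promoter of each species against the other.
#'
#' @param ds A `sim_dataset` or a list with the same fields (`promoters`,
#'   `alignment_status`, `expression` per species, `config$species` or
#'   `species`).
#' @param config A [classifier_config()].
#' @return List with `profiles` (combined data.frame), `outcomes`
#'   (combined), `lineage_table`, and per-species pieces.
#' @export
classify_dataset <- function(ds, config = classifier_config()) {
  sp <- ds$config$species %||% ds$species
  stopifnot(length(sp) == 2L)
  profiles <- lapply(sp, function(s) {
    expression_profiles(ds$expression[[s]]$matrix, ds$expression[[s]]$sheet)
  })
  names(profiles) <- sp
  outcomes <- lapply(1:2, function(si) {
    me <- sp[si]
    other <- sp[3L - si]
    classify_promoters(ds$promoters[[me]], ds$alignment_status[[me]],
                       profiles[[me]], ds$promoters[[other]],
                       profiles[[other]], other, config)
  })
  names(outcomes) <- sp
  all_profiles <- do.call(rbind, lapply(profiles, function(p) {
    p[, c("promoter_id", "species", "breadth", "median_tpm", "max_tpm",
          "biased_tissues", "biased_categories", "housekeeping")]
  }))
  rownames(all_profiles) <- NULL
  all_outcomes <- do.call(rbind, outcomes)
  rownames(all_outcomes) <- NULL
  list(profiles = all_profiles,
       profiles_by_species = profiles,
       outcomes = all_outcomes,
       outcomes_by_species = outcomes,
       lineage_table = lineage_count_table(all_outcomes,
                                           species_order = sp))
}

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  if (is.null(config$outdir)) stop("config field 'outdir' is required",
                                   call. = FALSE)
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config requires either 'simulate:' parameters or 'inputs:' paths",
         call. = FALSE)
  }
  config
}

#' Run the full promoter-turnover pipeline
#'
#' Stages run in dependency order: data (simulate or load), expression
#' profiling, turnover classification, gene-level aggregation, the derived
#' allele frequency test (skipped with a notice when no variants are
#' supplied), enrichment, and the report. A failure raises a stage-named
#' error. The manifest lists every output file with its checksum, the seeds
#' used, and per-stage counters.
#'
#' @param config Pipeline configuration: a list or path to a YAML file.
#'   Fields: `outdir`; `seed`; either `simulate:` ([sim_config()]
#'   parameters) or `inputs:` (paths per species); optional `classifier:`
#'   ([classifier_config()] parameters), `daf:` (`reference_counts`),
#'   `enrichment:` (`n_permutations`, `n_boot`).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list of class `ptk_run` with `report` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  config <- load_pipeline_config(config)
  seed <- seed %||% config$seed %||% 1L
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  counters <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- data -------------------------------------------------------------
  ds <- stage("data", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- derive_seed(seed, 1L)
      cfg <- do.call(sim_config, sim_args)
      ds <- simulate_dataset(cfg)
      write_dataset(ds, file.path(outdir, "data"))
      ds
    } else {
      load_dataset(config$inputs)
    }
  })
  sp <- ds$config$species %||% ds$species
  counters$promoters <- vapply(sp, function(s) nrow(ds$promoters[[s]]),
                               integer(1))

  cls_cfg <- do.call(classifier_config, config$classifier %||% list())

  # -- expression + classify -------------------------------------------
  cls <- stage("classify", classify_dataset(ds, cls_cfg))
  unclassified <- vapply(sp, function(s) {
    oc <- cls$outcomes_by_species[[s]]
    sum(oc$sequence_fate == "UNCLASSIFIED")
  }, integer(1))
  counters$unclassified <- unclassified
  counters$unclassified_pct <- vapply(sp, function(s) {
    format_percent(unclassified[[s]], nrow(ds$promoters[[s]]))
  }, numeric(1))
  conflict_calls <- sum(grepl("CONFLICT", cls$outcomes$evidence,
                              fixed = TRUE))
  counters$conflict_calls <- conflict_calls

  bias <- stage("classify", {
    tab <- cls$lineage_table
    if (all(tab[, "insertions"] > 0)) {
      deletion_bias_ratio(tab)
    } else {
      notices <- c(notices,
                    "deletion bias skipped: zero insertion count")
      NULL
    }
  })
  tissue_summary <- stage("classify",
                          tissue_outcome_summary(cls$outcomes,
                                                 cls$profiles))

  # -- genes ------------------------------------------------------------
  genes <- stage("genes", {
    all_prom <- do.call(rbind, lapply(sp, function(s) {
      ds$promoters[[s]][, c("promoter_id", "chrom", "start", "end",
                            "strand", "species", "promoter_class",
                            "gene_id")]
    }))
    summaries <- gene_turnover_summaries(cls$outcomes, all_prom,
                                         ds$orthologs, cls$profiles,
                                         species_order = sp)
    list(summaries = summaries, census = gene_category_census(summaries))
  })

  # -- daf --------------------------------------------------------------
  daf <- stage("daf", {
    if (is.null(ds$variants)) {
      notices <- c(notices, "daf stage skipped: no variants supplied")
      NULL
    } else {
      v <- ds$variants
      if (is.null(v$unresolved)) {
        v$unresolved <- !v$ancestral %in% c("A", "C", "G", "T")
      }
      snp <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
      counters$variants_dropped <- sum(!snp)
      v <- v[snp, , drop = FALSE]
      ref_counts <- config$daf$reference_counts %||%
        expected_reference_counts(
          total = 2e6,
          n_chrom = ds$config$n_sample_chromosomes %||% 2000L
        )
      test_set <- ds$promoters[[sp[1L]]]
      daf_test(test_set, v, ref_counts)
    }
  })

  # -- enrichment -------------------------------------------------------
  enr_cfg <- config$enrichment %||% list()
  n_perm <- enr_cfg$n_permutations %||% 200L
  enrich <- stage("enrich", {
    allowed <- allowed_regions(ds$mappable, ds$blacklist)
    out <- list()
    ocA <- cls$outcomes_by_species[[sp[1L]]]
    ins_ids <- ocA$promoter_id[ocA$sequence_fate == "INSERTED"]
    prA <- ds$promoters[[sp[1L]]]
    if (length(ins_ids) >= 5L && !is.null(ds$repeats)) {
      out$repeats <- repeat_enrichment(
        prA[prA$promoter_id %in% ins_ids, , drop = FALSE],
        ds$repeats[[sp[1L]]],
        background = "permuted_insertions",
        allowed = allowed,
        n_permutations = n_perm,
        n_boot = enr_cfg$n_boot %||% 1000L,
        seed = derive_seed(seed, 3L)
      )
    } else if (is.null(ds$repeats)) {
      notices <- c(notices, "repeat enrichment skipped: no repeats")
    } else {
      notices <- c(notices,
                    "repeat enrichment skipped: too few insertions")
    }
    if (!is.null(ds$conservation)) {
      aligned_ids <- ocA$promoter_id[ocA$sequence_fate == "ALIGNED"]
      anchors <- prA[prA$promoter_id %in% aligned_ids, , drop = FALSE]
      if (nrow(anchors) > 200L) anchors <- anchors[seq_len(200L), ]
      if (nrow(anchors) > 0L) {
        out$conservation <- score_profile(
          anchors, ds$conservation[[sp[1L]]],
          null = list(allowed = allowed, n_permutations = 50L,
                      seed = derive_seed(seed, 4L))
        )
      }
    }
    out
  })

  # -- report -----------------------------------------------------------
  report <- list(
    species = sp,
    outcome_table = outcome_census(cls$outcomes, sp),
    lineage_table = cls$lineage_table,
    deletion_bias = if (!is.null(bias)) {
      list(fold = bias$fold, p_value = bias$p_value)
    },
    unclassified_pct = as.list(counters$unclassified_pct),
    gene_census = as.list(genes$census$by_category),
    n_compensatory = sum(genes$summaries$compensatory),
    tissue_rho_biased_counts = tissue_summary$rho_biased_counts,
    daf = if (!is.null(daf)) {
      list(odds_ratio = daf$odds_ratio, ci = c(daf$ci_low, daf$ci_high),
           p_value = daf$p_value, n_informative = daf$n_informative)
    },
    repeat_enrichment = if (!is.null(enrich$repeats)) {
      list(fold = enrich$repeats$fold,
           observed = enrich$repeats$observed,
           null_mean = enrich$repeats$null_mean)
    },
    classifier_config = unclass(cls_cfg),
    notices = notices
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion(
      "promoterTurnover")),
    seed = seed,
    config = config[setdiff(names(config), "outdir")],
    counters = counters,
    notices = notices,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  res <- list(report = report, manifest = manifest,
              outcomes = cls$outcomes, gene_summaries = genes$summaries,
              daf = daf, enrichment = enrich)
  class(res) <- "ptk_run"
  invisible(res)
}

# Outcome census per species: counts of each fate/expression outcome.
outcome_census <- function(outcomes, species) {
  lab <- ifelse(outcomes$sequence_fate == "ALIGNED",
                paste0("ALIGNED_", outcomes$expression_outcome),
                outcomes$sequence_fate)
  tab <- table(outcomes$species, lab)
  out <- lapply(species, function(s) as.list(tab[s, , drop = TRUE]))
  names(out) <- species
  out
}

#' @export
print.ptk_run <- function(x, ...) {
  cat("Promoter turnover pipeline run\n")
  print(x$report$lineage_table)
  if (!is.null(x$report$deletion_bias)) {
    cat(sprintf("deletion bias fold: %.2f (p = %.3g)\n",
                x$report$deletion_bias$fold,
                x$report$deletion_bias$p_value))
  }
  if (length(x$report$notices)) {
    cat("notices:\n")
    for (n in x$report$notices) cat("  -", n, "\n")
  }
  invisible(x)
}

#' Load pipeline inputs from files
#'
#' @param inputs Named list with `species` (length-2 character) and, per
#'   species `s`: `promoters_<s>` (BED), `genemap_<s>`, `status_<s>`,
#'   `expression_<s>`, `samples_<s>`, optional `repeats_<s>`,
#'   `conservation_<s>`; plus `mappable`, `blacklist`, `orthologs`,
#'   optional `variants`.
#' @return A dataset list usable by [classify_dataset()] and
#'   [run_pipeline()].
#' @export
load_dataset <- function(inputs) {
  sp <- inputs$species
  if (is.null(sp) || length(sp) != 2L) {
    stop("inputs$species must name the two focal species", call. = FALSE)
  }
  need <- function(key) {
    path <- inputs[[key]]
    if (is.null(path)) stop("missing input: ", key, call. = FALSE)
    if (!file.exists(path)) stop("input file not found: ", path,
                                 call. = FALSE)
    path
  }
  ds <- list(species = sp, config = list(species = sp),
             promoters = list(), alignment_status = list(),
             expression = list(), repeats = NULL, conservation = NULL)
  for (s in sp) {
    ds$promoters[[s]] <- read_promoters(need(paste0("promoters_", s)), s,
                                        inputs[[paste0("genemap_", s)]])
    ds$alignment_status[[s]] <-
      read_alignment_status(need(paste0("status_", s)))
    ds$expression[[s]] <- read_expression(need(paste0("expression_", s)),
                                          need(paste0("samples_", s)))
    rp <- inputs[[paste0("repeats_", s)]]
    if (!is.null(rp)) {
      bed <- utils::read.table(rp, sep = "\t", stringsAsFactors = FALSE)
      ds$repeats[[s]] <- data.frame(chrom = bed[[1L]], start = bed[[2L]],
                                    end = bed[[3L]],
                                    family = bed[[min(7L, ncol(bed))]],
                                    stringsAsFactors = FALSE)
    }
    cons <- inputs[[paste0("conservation_", s)]]
    if (!is.null(cons)) ds$conservation[[s]] <- read_bedgraph(cons)
  }
  ds$mappable <- read_bed(need("mappable"))
  ds$blacklist <- read_bed(need("blacklist"))
  ds$orthologs <- read_orthologs(need("orthologs"))
  if (!is.null(inputs$variants)) {
    ds$variants <- read_variants(inputs$variants)
  }
  ds
}
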