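#' Pipeline configuration
#'
#' Describes one end-to-end run: either a simulation (`simulate` holds a
#' [sim_config()]) or real inputs (`vcf_path`, optional
#' `annotation_path`, `outgroup_samples` naming the outgroup columns of
#' the VCF).  Stage-specific SNP sets follow the usual per-analysis filter
#' matrix: the MAF filter applies to the kinship / LD-pruning / Ne set but
#' not to the diversity / ROH / load set, whose spectra ROH structure and
#' counts it would distort (each toggleable).
#'
#' @param simulate optional [sim_config()] for simulate-mode.
#' @param vcf_path,annotation_path,outgroup_samples real-data inputs
#'   (ignored in simulate-mode).
#' @param filter a [filter_config()].
#' @param ld_prune an [ld_prune_config()].
#' @param roh a [roh_params()].
#' @param rec a [recombination_model()].
#' @param genome_length autosome length for FROH.
#' @param maf_for_diversity apply the MAF filter to the diversity /
#'   ROH / load SNP set too (default `FALSE`).
#' @param exclude_flagged_relatives drop one member of every `flagged`
#'   pair (the second sample of the pair) before the downstream stages.
#' @param ne_pairs inter-chromosomal pairs for [interchrom_r2()].
#' @param ne_correction sampling-floor convention for the Ne estimators
#'   (see [ne_unlinked()]); the pipeline defaults to the small-sample
#'   exact null `"1/(n-1)"`.
#' @param stages character subset of
#'   `c("kinship","diversity","roh","ne","load")` to run.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir output directory for the report bundle (`NULL` for none).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, vcf_path = NULL,
                            annotation_path = NULL, outgroup_samples = NULL,
                            filter = filter_config(),
                            ld_prune = ld_prune_config(),
                            roh = roh_params(),
                            rec = recombination_model(),
                            genome_length = 2222501653,
                            maf_for_diversity = FALSE,
                            exclude_flagged_relatives = FALSE,
                            ne_pairs = 20000,
                            ne_correction = "1/(n-1)",
                            stages = c("kinship", "diversity", "roh", "ne",
                                       "load"),
                            seed = 1, out_dir = NULL) {
  if (is.null(simulate) && is.null(vcf_path))
    stop("either a sim_config or a vcf_path is required")
  if (!is.null(vcf_path) && is.null(simulate) && !file.exists(vcf_path))
    stop("vcf_path does not exist: ", vcf_path)
  structure(list(simulate = simulate, vcf_path = vcf_path,
                 annotation_path = annotation_path,
                 outgroup_samples = outgroup_samples, filter = filter,
                 ld_prune = ld_prune, roh = roh, rec = rec,
                 genome_length = genome_length,
                 maf_for_diversity = maf_for_diversity,
                 exclude_flagged_relatives = exclude_flagged_relatives,
                 ne_pairs = ne_pairs, ne_correction = ne_correction,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the erosion pipeline end to end
#'
#' Stage order: acquire (simulate or read) -> site filters -> kinship
#' (with optional exclusion of flagged relatives) -> diversity, ROH, Ne
#' and load on the appropriate SNP sets.  All randomness derives from the
#' config seed, so a rerun with the same config is identical.  When
#' `out_dir` is set, every stage output is written as TSV together with a
#' JSON run manifest (package version, seed, config echo, per-stage
#' site/sample counts).
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `variants`
#'   (filtered, no-MAF set), `variants_maf`, `filter_report`, `kinship`,
#'   `excluded_samples`, `ho`, `sfs`, `pi`, `roh_segments`,
#'   `roh_profile`, `ne`, `ne_trajectory`, `load`, `polarization_report`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max, 8)
  counts <- list()
  res <- list()

  # --- acquire ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    .stage_log("acquire", "simulating (seed %d)", config$simulate$seed)
    sim <- simulate_population(config$simulate)
    vt <- sim$variants
    ann <- sim_annotations(sim)
    ogb <- outgroup_alleles(sim)
    res$sim_truth <- sim$truth
  } else {
    .stage_log("acquire", "reading %s", config$vcf_path)
    vt <- read_vcf(config$vcf_path, config$annotation_path)
    if (!is.null(config$outgroup_samples))
      vt$populations[vt$samples %in% config$outgroup_samples] <- "OUT"
    ann <- vt$annotation
    ogb <- NULL
    if (length(og <- which(vt$populations == "OUT"))) {
      g <- vt$geno[, og[1:min(2, length(og))], drop = FALSE]
      ogb <- matrix(NA_character_, n_sites(vt), ncol(g))
      for (k in seq_len(ncol(g)))
        ogb[, k] <- ifelse(is.na(g[, k]), NA_character_,
                           ifelse(g[, k] == 0L, vt$ref,
                                  ifelse(g[, k] == 2L, vt$alt,
                                         NA_character_)))
    }
  }
  vt$annotation <- NULL
  counts$input <- c(sites = n_sites(vt), samples = n_samples(vt))

  # --- site filters ----------------------------------------------------
  base_cfg <- config$filter
  maf_cfg <- base_cfg
  base_cfg$maf_min <- 0
  f_base <- apply_site_filters(vt, base_cfg)
  f_maf <- apply_site_filters(f_base$variants, maf_cfg)
  vt_base <- if (config$maf_for_diversity) f_maf$variants
             else f_base$variants
  vt_maf <- f_maf$variants
  keep_base <- match(paste(vt_base$chrom, vt_base$pos),
                     paste(vt$chrom, vt$pos))
  .stage_log("filter", "%d -> %d sites (no-MAF set), %d (MAF set)",
             n_sites(vt), n_sites(vt_base), n_sites(vt_maf))
  res$filter_report <- f_base$report
  res$filter_report_maf <- f_maf$report
  counts$filter <- c(no_maf = n_sites(vt_base), maf = n_sites(vt_maf))

  # --- kinship ---------------------------------------------------------
  excluded <- character()
  if ("kinship" %in% config$stages) {
    kin <- flag_related(kinship_all(vt_maf))
    res$kinship <- kin
    if (config$exclude_flagged_relatives) {
      excluded <- unique(kin$sample_j[kin$flag == "flagged"])
      if (length(excluded)) {
        .stage_log("kinship", "excluding %s",
                   paste(excluded, collapse = ", "))
        keep_s <- setdiff(seq_len(n_samples(vt_base)),
                          match(excluded, vt_base$samples))
        vt_base <- subset_variants(vt_base, samples = keep_s)
        vt_maf <- subset_variants(
          vt_maf, samples = setdiff(seq_len(n_samples(vt_maf)),
                                    match(excluded, vt_maf$samples)))
      }
    }
    .stage_log("kinship", "%d pairs, %d flagged, %d advisory",
               nrow(kin), sum(kin$flag == "flagged"),
               sum(kin$flag == "advisory"))
  }
  res$excluded_samples <- excluded
  counts$kinship <- c(samples_kept = length(ingroup_samples(vt_base)))

  # --- diversity -------------------------------------------------------
  if ("diversity" %in% config$stages) {
    ing <- ingroup_samples(vt_base)
    res$ho <- data.frame(
      sample = vt_base$samples[ing],
      ho = vapply(ing, function(s)
        individual_heterozygosity(vt_base, s), 0))
    res$sfs <- folded_sfs(vt_base)
    res$pi <- windowed_pi(vt_base)
    .stage_log("diversity", "mean Ho (variant sites) = %.4f",
               mean(res$ho$ho))
  }

  # --- roh -------------------------------------------------------------
  if ("roh" %in% config$stages) {
    segs <- call_roh_all(vt_base, params = config$roh)
    res$roh_segments <- segs
    res$roh_profile <- summarize_roh(
      segs, genome_length = config$genome_length,
      samples = vt_base$samples[ingroup_samples(vt_base)])
    .stage_log("roh", "%d segments, mean FROH = %.4f", nrow(segs),
               mean(res$roh_profile$FROH))
  }

  # --- ne --------------------------------------------------------------
  if ("ne" %in% config$stages && length(unique(vt_maf$chrom)) >= 2) {
    icr <- interchrom_r2(vt_maf, n_pairs = config$ne_pairs,
                         seed = stage_seed[4])
    res$ne <- ne_unlinked(icr$mean_r2, icr$n_individuals,
                          correction = config$ne_correction)
    res$ne_trajectory <- ne_trajectory(
      vt_maf, rec = config$rec, seed = stage_seed[5],
      correction = config$ne_correction)
    .stage_log("ne", "contemporary Ne = %s",
               if (is.na(res$ne$ne)) "undefined"
               else sprintf("%.1f", res$ne$ne))
  }

  # --- load ------------------------------------------------------------
  if ("load" %in% config$stages && !is.null(ogb) && !is.null(ann)) {
    ann_b <- ann[keep_base[!is.na(keep_base)], ]
    ogb_b <- ogb[keep_base[!is.na(keep_base)], , drop = FALSE]
    pol <- polarize(vt_base, ogb_b, seed = stage_seed[6])
    ori <- orient_derived(pol, vt_base)
    cats <- classify_impact(ann_b)
    res$load <- load_counts(vt_base, cats, keep = ori$keep)
    res$polarization <- pol
    res$polarization_report <- ori$report
    .stage_log("load", "%d sites retained for load accounting",
               length(ori$keep))
  }

  res$variants <- vt_base
  res$variants_maf <- vt_maf
  res$manifest <- list(
    package = "poperosion",
    version = as.character(utils::packageVersion("poperosion")),
    seed = config$seed,
    config = .echo_config(config),
    counts = counts)
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) .write_bundle(res, config$out_dir)
  res
}

.echo_config <- function(config) {
  cfg <- unclass(config)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  cfg$out_dir <- NULL
  cfg
}

.write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x))
    data.table::fwrite(as.data.frame(x), file.path(dir, name), sep = "\t")
  wr(res$filter_report, "filter_report.tsv")
  wr(res$kinship, "kinship.tsv")
  wr(res$ho, "heterozygosity.tsv")
  wr(res$pi, "windowed_pi.tsv")
  wr(res$roh_segments, "roh_segments.tsv")
  wr(res$roh_profile, "roh_profile.tsv")
  wr(res$ne_trajectory, "ne_trajectory.tsv")
  wr(res$load, "load.tsv")
  wr(res$polarization_report, "polarization_report.tsv")
  if (!is.null(res$ne))
    data.table::fwrite(data.frame(method = res$ne$method, ne = res$ne$ne,
                                  mean_r2 = res$ne$mean_r2,
                                  n = res$ne$n_individuals,
                                  correction = res$ne$correction),
                       file.path(dir, "ne.tsv"), sep = "\t")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d sites (no-MAF set), %d ingroup samples\n",
              n_sites(x$variants), length(ingroup_samples(x$variants))))
  if (!is.null(x$ne)) print(x$ne)
  if (!is.null(x$roh_profile))
    cat(sprintf("  mean FROH = %.4f\n", mean(x$roh_profile$FROH)))
  invisible(x)
}
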