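#' ROH caller parameters
#'
#' Defaults reproduce the common PLINK `--homozyg` setup for non-model
#' species: minimum run length 100 kb (`--homozyg-kb 100`), at least 100
#' SNPs (`--homozyg-snp 100`), density of at most 50 kb per SNP
#' (`--homozyg-density 50`), 50-SNP scanning windows tolerating 1
#' heterozygous and 5 missing calls (`--homozyg-window-het 1`,
#' `--homozyg-window-missing 5`), runs split at inter-SNP gaps above
#' 1000 kb (`--homozyg-gap 1000`), and a window hit-fraction threshold of
#' 0.05 (`--homozyg-window-threshold`).
#'
#' @param min_kb minimum reported segment length (kb).
#' @param min_snps minimum SNPs per segment.
#' @param max_kb_per_snp maximum average kb per SNP inside a segment.
#' @param window_snps scanning window size in SNPs.
#' @param window_het_max,window_missing_max tolerated het / missing calls
#'   per window.
#' @param gap_kb split runs when adjacent SNPs are farther apart than this.
#' @param hit_threshold minimum fraction of overlapping windows that must
#'   be homozygous-accepted for a SNP to be ROH-eligible; in `(0, 1]`.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_kb = 100, min_snps = 100, max_kb_per_snp = 50,
                       window_snps = 50, window_het_max = 1,
                       window_missing_max = 5, gap_kb = 1000,
                       hit_threshold = 0.05) {
  stopifnot(min_kb > 0, min_snps > 0, max_kb_per_snp > 0, window_snps > 0,
            gap_kb > 0, hit_threshold > 0, hit_threshold <= 1)
  structure(list(min_kb = min_kb, min_snps = min_snps,
                 max_kb_per_snp = max_kb_per_snp, window_snps = window_snps,
                 window_het_max = window_het_max,
                 window_missing_max = window_missing_max, gap_kb = gap_kb,
                 hit_threshold = hit_threshold), class = "roh_params")
}

#' Call runs of homozygosity for one sample
#'
#' Window-based detection: (1) every contiguous block of `window_snps`
#' SNPs is accepted iff it holds at most `window_het_max` heterozygous and
#' `window_missing_max` missing calls; (2) a SNP's hit fraction is the
#' share of accepted windows among the windows that actually cover it
#' (chromosome ends therefore have fewer, not phantom, windows), and the
#' SNP is eligible iff that fraction reaches `hit_threshold`; (3) maximal
#' runs of eligible SNPs are split where adjacent SNPs are more than
#' `gap_kb` apart; (4) runs are reported iff they satisfy the length, SNP
#' count and density criteria.  Segment endpoints are the outermost
#' eligible SNP positions; `length = end - start + 1`.
#'
#' @param vt a [variant_table()].
#' @param sample sample index or id.
#' @param params a [roh_params()].
#' @return A `data.frame` of segments: `sample`, `chrom`, `start`, `end`,
#'   `length_bp`, `n_snps`, `n_het`.  Chromosomes with fewer than
#'   `window_snps` sites yield no calls (with a message).
#' @export
call_roh <- function(vt, sample, params = roh_params()) {
  if (is.character(sample)) sample <- match(sample, vt$samples)
  ws <- params$window_snps
  segs <- list()
  for (cc in unique(vt$chrom)) {
    idx <- which(vt$chrom == cc)
    M <- length(idx)
    if (M < ws) {
      message(sprintf("call_roh: chromosome %s has %d < %d SNPs; skipped",
                      cc, M, ws))
      next
    }
    d <- vt$geno[idx, sample]
    p <- as.numeric(vt$pos[idx])
    het <- !is.na(d) & d == 1L
    mis <- is.na(d)
    W <- M - ws + 1L
    csh <- c(0L, cumsum(het)); csm <- c(0L, cumsum(mis))
    wstart <- seq_len(W)
    acc <- (csh[wstart + ws] - csh[wstart]) <= params$window_het_max &
           (csm[wstart + ws] - csm[wstart]) <= params$window_missing_max
    ca <- c(0L, cumsum(acc))
    i <- seq_len(M)
    lo <- pmax(1L, i - ws + 1L)
    hi <- pmin(i, W)
    frac <- (ca[hi + 1L] - ca[lo]) / (hi - lo + 1L)
    elig <- frac >= params$hit_threshold
    ie <- which(elig)
    if (!length(ie)) next
    newrun <- c(TRUE, diff(ie) > 1L |
                  (p[ie][-1] - p[ie][-length(ie)]) > params$gap_kb * 1000)
    gid <- cumsum(newrun)
    for (g in unique(gid)) {
      m <- ie[gid == g]
      start <- p[m[1]]; end <- p[m[length(m)]]
      len <- end - start + 1
      nsnp <- length(m)
      if (len >= params$min_kb * 1000 && nsnp >= params$min_snps &&
          len / nsnp <= params$max_kb_per_snp * 1000) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample = vt$samples[sample], chrom = cc, start = start,
          end = end, length_bp = len, n_snps = nsnp, n_het = sum(het[m]))
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      length_bp = numeric(), n_snps = integer(),
                      n_het = integer()))
  do.call(rbind, segs)
}

#' @rdname call_roh
#' @param samples sample index for [call_roh_all()] (defaults to ingroup).
#' @export
call_roh_all <- function(vt, samples = NULL, params = roh_params()) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  do.call(rbind, lapply(samples, function(s) call_roh(vt, s, params)))
}

.roh_class <- function(length_bp) {
  cut(length_bp, c(-Inf, 1e5, 1e6, 1e7, Inf),
      labels = c("sub_short", "short", "intermediate", "long"),
      right = FALSE)  # boundary lengths go to the longer class
}

#' Per-individual ROH profile: NROH, SROH, FROH and size classes
#'
#' `FROH = SROH / genome_length`, the genomic inbreeding coefficient.  The
#' size classes are short (100 kb to 1 Mb), intermediate (1 to 10 Mb) and
#' long (above 10 Mb); a boundary length is assigned to the longer class.
#'
#' @param segments segment `data.frame` from [call_roh()]/[call_roh_all()].
#' @param genome_length autosomal genome length covered by SNP positions,
#'   in bp; the default is the canid autosome total used for
#'   whole-genome wolf data.
#' @param samples optional sample ids to force into the output (zero rows
#'   of `segments` still produce a profile of zeros).
#' @return A `data.frame` per sample: `NROH`, `SROH`, `FROH`,
#'   `SROH_short`, `SROH_intermediate`, `SROH_long`.
#' @export
summarize_roh <- function(segments, genome_length = 2222501653,
                          samples = NULL) {
  if (genome_length <= 0) stop("genome_length must be positive")
  samples <- samples %||% unique(segments$sample)
  cls <- .roh_class(segments$length_bp)
  rows <- lapply(samples, function(s) {
    m <- segments$sample == s
    sroh <- sum(segments$length_bp[m])
    data.frame(sample = s, NROH = sum(m), SROH = sroh,
               FROH = sroh / genome_length,
               SROH_short = sum(segments$length_bp[m & cls == "short"]),
               SROH_intermediate =
                 sum(segments$length_bp[m & cls == "intermediate"]),
               SROH_long = sum(segments$length_bp[m & cls == "long"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Constant-rate recombination model
#'
#' @param rate recombination rate in cM per Mb; the default 1.3459 is the
#'   genome-wide average for the dog genome assembly used as reference for
#'   wolf data.
#' @return A list of class `recombination_model`.
#' @export
recombination_model <- function(rate = 1.3459) {
  stopifnot(rate > 0)
  structure(list(rate = rate), class = "recombination_model")
}

#' Coalescence-time dating of a ROH
#'
#' Under the expected IBD-segment length relation `L = 100 / (2 t)` cM, a
#' run of physical length `length_bp` maps to `t = 100 / (2 L_cM)`
#' generations with `L_cM = length_bp / 1e6 * rate`.  The unrounded value
#' is returned; round to the nearest integer generation for presentation.
#'
#' @param length_bp ROH length in bp (> 0).
#' @param rec a [recombination_model()].
#' @return Time in generations (numeric, unrounded).
#' @examples
#' round(roh_age(1e6))   # 37 generations for a 1 Mb run
#' round(roh_age(1e7))   # 4 generations for a 10 Mb run
#' @export
roh_age <- function(length_bp, rec = recombination_model()) {
  if (any(length_bp <= 0)) stop("ROH length must be positive")
  l_cm <- length_bp / 1e6 * rec$rate
  100 / (2 * l_cm)
}

#' Expected ROH length for a coalescence time
#'
#' Exact inverse of [roh_age()]: `length_bp = 100 / (2 t) / rate * 1e6`.
#'
#' @param t time in generations (> 0).
#' @param rec a [recombination_model()].
#' @return Length in bp.
#' @export
length_for_age <- function(t, rec = recombination_model()) {
  if (any(t <= 0)) stop("generation count must be positive")
  100 / (2 * t) / rec$rate * 1e6
}

#' Fraction of population SROH attributable to a bottleneck window
#'
#' Segments whose lengths date (via [roh_age()]) to between `g_old`
#' generations ago and `post_gens` generations after the bottleneck ended
#' (`g_recent - post_gens`) are pooled over all samples and their summed
#' length is divided by the total SROH.  The corresponding length band is
#' `[length_for_age(g_old), length_for_age(g_recent - post_gens)]`,
#' inclusive.
#'
#' @param segments segment `data.frame` (pooled population).
#' @param g_old,g_recent bottleneck start / end, generations before
#'   present (`g_old > g_recent`).
#' @param post_gens generations after the bottleneck still attributed to
#'   it (default 5).
#' @param rec a [recombination_model()].
#' @return Fraction in `[0, 1]`; `NA` for an empty segment set.
#' @export
bottleneck_window_fraction <- function(segments, g_old, g_recent,
                                       post_gens = 5,
                                       rec = recombination_model()) {
  stopifnot(g_old > g_recent, g_recent >= post_gens, post_gens >= 0)
  if (is.null(segments) || nrow(segments) == 0) return(.undefined)
  band <- c(length_for_age(g_old, rec),
            length_for_age(g_recent - post_gens, rec))
  inside <- segments$length_bp >= band[1] & segments$length_bp <= band[2]
  sum(segments$length_bp[inside]) / sum(segments$length_bp)
}

#' Convert generations before present to a calendar year
#'
#' @param g generations before the reference year (>= 0).
#' @param gen_years generation time in years (> 0).
#' @param reference_year anchor year.
#' @return `reference_year - g * gen_years`.
#' @examples
#' generations_to_years(18, 4, 2010)  # 1938
#' @export
generations_to_years <- function(g, gen_years, reference_year) {
  stopifnot(all(g >= 0), gen_years > 0)
  reference_year - g * gen_years
}
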