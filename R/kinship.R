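#' Shared-genotype counts for a sample pair
#'
#' Counts, over sites where both calls are non-missing: opposite homozygotes
#' (IBS0), double heterozygotes, and per-member heterozygote totals.  These
#' are the sufficient statistics for the KING-robust kinship estimator and
#' the R0/R1 relatedness ratios.
#'
#' @param vt a [variant_table()].
#' @param i,j sample indices or ids.
#' @return A list with `n_sites`, `n_ibs0`, `n_hethet`, `n_het_i`,
#'   `n_het_j`; errors when no pairwise-complete site exists.
#' @export
pair_counts <- function(vt, i, j) {
  if (is.character(i)) i <- match(i, vt$samples)
  if (is.character(j)) j <- match(j, vt$samples)
  x <- vt$geno[, i]; y <- vt$geno[, j]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no pairwise-complete sites for this pair")
  x <- x[ok]; y <- y[ok]
  list(n_sites = sum(ok),
       n_ibs0 = sum((x == 0L & y == 2L) | (x == 2L & y == 0L)),
       n_hethet = sum(x == 1L & y == 1L),
       n_het_i = sum(x == 1L),
       n_het_j = sum(y == 1L))
}

#' KING-robust kinship and the R0 / R1 relatedness ratios
#'
#' `king_phi` is the within-pair KING-robust kinship estimate
#' `(n_hethet - 2 n_ibs0) / (n_het_i + n_het_j)`; 0.5 for duplicates/self,
#' ~0.25 for parent-offspring, ~0 for unrelated pairs.  `king_r0` is
#' `n_ibs0 / n_hethet` (0 for true parent-offspring pairs) and `king_r1` is
#' `n_hethet / (n_het_i + n_het_j - 2 n_hethet + n_ibs0)`: double
#' heterozygotes over genotype-discordant sites, the convention under
#' which a parent-offspring pair has expectation exactly 0.5 at every
#' allele frequency (see the methods vignette).  Degenerate denominators
#' yield `NA`.
#'
#' @param counts output of [pair_counts()].
#' @return A single numeric value (`NA` when undefined).
#' @export
king_phi <- function(counts) {
  d <- counts$n_het_i + counts$n_het_j
  if (d == 0) return(.undefined)
  (counts$n_hethet - 2 * counts$n_ibs0) / d
}

#' @rdname king_phi
#' @export
king_r0 <- function(counts) {
  if (counts$n_hethet == 0) return(.undefined)
  counts$n_ibs0 / counts$n_hethet
}

#' @rdname king_phi
#' @export
king_r1 <- function(counts) {
  d <- counts$n_het_i + counts$n_het_j - 2 * counts$n_hethet +
    counts$n_ibs0
  if (d == 0) return(.undefined)
  counts$n_hethet / d
}

#' Pairwise relatedness over all ingroup sample pairs
#'
#' @param vt a [variant_table()].
#' @param samples optional sample index (defaults to ingroup).
#' @return A `data.frame` with one row per unordered pair: `sample_i`,
#'   `sample_j`, `n_sites`, `n_ibs0`, `n_hethet`, `phi`, `R0`, `R1`.
#' @export
kinship_all <- function(vt, samples = NULL) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  pairs <- utils::combn(samples, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ct <- pair_counts(vt, i, j)
    data.frame(sample_i = vt$samples[i], sample_j = vt$samples[j],
               n_sites = ct$n_sites, n_ibs0 = ct$n_ibs0,
               n_hethet = ct$n_hethet,
               phi = king_phi(ct), R0 = king_r0(ct), R1 = king_r1(ct))
  })
  do.call(rbind, rows)
}

#' Flag closely related sample pairs
#'
#' A pair is `"flagged"` when all three conditions hold: kinship
#' `phi >= phi_min`, `R0 <= r0_max` and `R1 >= r1_min`.  When exactly two
#' of the three hold, the pair receives an `"advisory"` flag (the
#' borderline case that still warrants manual review); otherwise `"none"`.
#' `NA` statistics count as not holding.  Flagged individuals are reported,
#' never dropped: exclusion is a pipeline choice
#' (see [pipeline_config()]).
#'
#' @param results data.frame from [kinship_all()].
#' @param phi_min,r0_max,r1_min thresholds (defaults 0.20 / 0.1 / 0.5).
#' @return `results` with an added `flag` column.
#' @export
flag_related <- function(results, phi_min = 0.20, r0_max = 0.1,
                         r1_min = 0.5) {
  hits <- (!is.na(results$phi) & results$phi >= phi_min) +
          (!is.na(results$R0) & results$R0 <= r0_max) +
          (!is.na(results$R1) & results$R1 >= r1_min)
  results$flag <- c("none", "none", "advisory", "flagged")[hits + 1L]
  results
}
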