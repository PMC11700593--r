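#' Individual observed heterozygosity
#'
#' `Ho = (# heterozygous calls) / denominator`.  The denominator defaults
#' to the number of non-missing calls of the sample at the assessed sites;
#' pass `callable_total` to normalize a variant-only table by a
#' genome-wide callable-site count instead (which is how a per-bp
#' heterozygosity is obtained from a SNP-only VCF).
#'
#' @param vt a [variant_table()].
#' @param sample sample index or id.
#' @param callable_total optional externally known callable-site total.
#' @return Ho in `[0, 1]` (or a small per-bp rate when `callable_total` is
#'   a genome length); errors on a zero denominator.
#' @export
individual_heterozygosity <- function(vt, sample, callable_total = NULL) {
  if (is.character(sample)) sample <- match(sample, vt$samples)
  g <- vt$geno[, sample]
  denom <- callable_total %||% sum(!is.na(g))
  if (is.null(denom) || denom <= 0) stop("zero callable sites")
  sum(g == 1L, na.rm = TRUE) / denom
}

#' Folded site frequency spectrum
#'
#' Per site, the minor-allele count among non-missing alleles increments
#' its bin; bins run from 0 to `floor(max alleles / 2)`.  The bin total
#' equals the number of sites.
#'
#' @param vt a [variant_table()].
#' @param samples optional sample index (defaults to ingroup).
#' @return Named integer vector over minor-allele counts `0..n_alleles/2`.
#' @export
folded_sfs <- function(vt, samples = NULL) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  stopifnot(length(samples) >= 1)
  g <- vt$geno[, samples, drop = FALSE]
  ac <- rowSums(g, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(g))
  mac <- pmin(ac, an - ac)
  nbin <- floor(2L * length(samples) / 2) + 1L
  sfs <- tabulate(mac + 1L, nbins = nbin)
  names(sfs) <- 0:(nbin - 1L)
  sfs
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is `pi_site = 2 c (n - c) / (n (n - 1))` with `c` the
#' alt-allele count and `n` the non-missing allele count; windows are
#' non-overlapping `window_bp` tiles and a window's pi is the sum of its
#' per-site values divided by the *full* window length (the convention of
#' the common windowed-pi tools, so monomorphic positions dilute the
#' estimate).  Sites with fewer than 2 called alleles are skipped and
#' counted in the `skipped_sites` attribute.
#'
#' @param vt a [variant_table()] (sorted; enforced at construction).
#' @param samples optional sample index (defaults to ingroup).
#' @param window_bp window size in bp (default 100 kb).
#' @param chrom_lengths optional named chromosome lengths used to tile to
#'   the chromosome ends; defaults to the largest observed position.
#' @return A `data.frame` with `chrom`, `start0` (0-based half-open
#'   window start), `end`, `n_variants`, `pi`.
#' @export
windowed_pi <- function(vt, samples = NULL, window_bp = 100000,
                        chrom_lengths = NULL) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  g <- vt$geno[, samples, drop = FALSE]
  ac <- rowSums(g, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(g))
  usable <- an >= 2
  pi_site <- rep(0, n_sites(vt))
  pi_site[usable] <- 2 * ac[usable] * (an[usable] - ac[usable]) /
    (an[usable] * (an[usable] - 1))
  out <- list()
  for (cc in unique(vt$chrom)) {
    idx <- which(vt$chrom == cc & usable)
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[cc]]
           else max(vt$pos[vt$chrom == cc])
    nwin <- ceiling(len / window_bp)
    wi <- (vt$pos[idx] - 1L) %/% window_bp + 1L
    psum <- rep(0, nwin); nv <- rep(0L, nwin)
    if (length(idx)) {
      agg <- rowsum(cbind(pi_site[idx], (ac[idx] > 0 & ac[idx] < an[idx])),
                    wi)
      w <- as.integer(rownames(agg))
      psum[w] <- agg[, 1]; nv[w] <- as.integer(agg[, 2])
    }
    out[[cc]] <- data.frame(chrom = cc,
                            start0 = (seq_len(nwin) - 1L) * window_bp,
                            end = pmin(seq_len(nwin) * window_bp, len),
                            n_variants = nv, pi = psum / window_bp)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped_sites") <- sum(!usable)
  res
}
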