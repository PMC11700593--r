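#' Mean r-squared over random inter-chromosomal site pairs
#'
#' Uniformly samples (with replacement, seeded) `n_pairs` site pairs lying
#' on different chromosomes and averages the squared genotype correlation
#' over the pairs where it is defined.  Inter-chromosomal LD carries no
#' recombination signal, so its drift component reflects effective size in
#' the most recent generations.
#'
#' @param vt a [variant_table()].
#' @param n_pairs number of pairs to draw.
#' @param seed RNG seed (same seed, same pair sample).
#' @param samples optional sample index (defaults to ingroup).
#' @return A list: `mean_r2`, `n_pairs` (defined pairs used),
#'   `n_individuals`.
#' @export
interchrom_r2 <- function(vt, n_pairs = 50000, seed = 1, samples = NULL) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  chroms <- unique(vt$chrom)
  poly <- vapply(chroms, function(cc) {
    idx <- which(vt$chrom == cc)
    any(site_maf(subset_variants(vt, idx, samples)) > 0, na.rm = TRUE)
  }, TRUE)
  if (sum(poly) < 2)
    stop("need >= 2 chromosomes with polymorphic sites for ",
         "inter-chromosomal pairs")
  set.seed(seed)
  S <- n_sites(vt)
  ci <- match(vt$chrom, chroms)
  ii <- integer(0); jj <- integer(0)
  while (length(ii) < n_pairs) {
    need <- n_pairs - length(ii)
    a <- sample.int(S, 2 * need + 10, replace = TRUE)
    b <- sample.int(S, 2 * need + 10, replace = TRUE)
    ok <- ci[a] != ci[b]
    ii <- c(ii, a[ok]); jj <- c(jj, b[ok])
  }
  ii <- ii[seq_len(n_pairs)]; jj <- jj[seq_len(n_pairs)]
  r2v <- .pair_r2(vt$geno[, samples, drop = FALSE], ii, jj)
  list(mean_r2 = mean(r2v, na.rm = TRUE), n_pairs = sum(!is.na(r2v)),
       n_individuals = length(samples))
}

# vectorized r^2 for index pair vectors; falls back to pairwise-complete
# computation when the genotype matrix has missing calls
.pair_r2 <- function(g, ii, jj) {
  if (!anyNA(g)) {
    x <- g - rowMeans(g)
    ss <- rowSums(x^2)
    num <- rowSums(x[ii, , drop = FALSE] * x[jj, , drop = FALSE])
    den <- ss[ii] * ss[jj]
    out <- ifelse(den > 0, num^2 / den, NA_real_)
    return(out)
  }
  vapply(seq_along(ii), function(k) {
    x <- g[ii[k], ]; y <- g[jj[k], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)^2
  }, 0)
}

.r2_floor <- function(n, correction) {
  switch(correction,
         "1/n" = 1 / n,
         "1/(n-1)" = 1 / (n - 1),
         stop("unknown correction: ", correction))
}

#' Contemporary Ne from unlinked-locus drift LD
#'
#' The classical drift-LD relation for unlinked loci,
#' `E[r2] ~ 1/(3 Ne) + sampling floor`, inverted:
#' `Ne = 1 / (3 (mean_r2 - floor))`.  The sampling floor defaults to the
#' conventional `1/n`; `correction = "1/(n-1)"` uses the exact null
#' expectation of squared Pearson correlation between independent dosage
#' vectors, which matters for small samples (see the methods vignette).
#' When the drift residual is non-positive the estimate is undefined (the
#' sample is too small to resolve the population).
#'
#' @param mean_r2 mean inter-chromosomal r^2 (e.g. from
#'   [interchrom_r2()]).
#' @param n_individuals number of diploid individuals behind `mean_r2`.
#' @param correction sampling-floor convention, `"1/n"` (default) or
#'   `"1/(n-1)"`.
#' @return A list of class `ne_estimate`: `method`, `ne` (`NA` when
#'   undefined), `mean_r2`, `r2_drift`, `n_individuals`, `correction`.
#' @export
ne_unlinked <- function(mean_r2, n_individuals,
                        correction = c("1/n", "1/(n-1)")) {
  correction <- match.arg(correction)
  stopifnot(mean_r2 > 0, n_individuals >= 2)
  drift <- mean_r2 - .r2_floor(n_individuals, correction)
  ne <- if (drift <= 0) .undefined else 1 / (3 * drift)
  structure(list(method = "unlinked_drift_ld", ne = ne, mean_r2 = mean_r2,
                 r2_drift = drift, n_individuals = n_individuals,
                 correction = correction),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> method=%s  Ne=%s  (mean r2=%.5g, n=%d, %s)\n",
              x$method,
              if (is.na(x$ne)) "undefined" else sprintf("%.1f", x$ne),
              x$mean_r2, x$n_individuals, x$correction))
  invisible(x)
}

#' Recent-history Ne trajectory from distance-binned LD
#'
#' Within-chromosome site pairs are sampled per recombination-distance bin
#' (physical distance mapped to Morgans through the constant-rate
#' [recombination_model()]), and each bin's mean r^2 is inverted through
#' the Sved relation `E[r2] = 1/(1 + 4 Ne c) + floor`, giving
#' `Ne(c) = (1/r2_drift - 1) / (4 c)` at a time depth of roughly
#' `t = 1/(2 c)` generations.  Bins whose drift residual is non-positive,
#' or with fewer than `min_pairs` sampled pairs, are dropped with a
#' diagnostic message.
#'
#' @param vt a [variant_table()].
#' @param rec a [recombination_model()].
#' @param c_bins increasing vector of bin edges in Morgans; default 20
#'   log-spaced bins over `[5e-4, 0.05]` (t of about 10 to 1000
#'   generations).
#' @param n_individuals number of diploid individuals (defaults to the
#'   ingroup count).
#' @param n_pairs_per_bin pairs sampled per bin.
#' @param min_pairs minimum defined pairs for a bin to be reported.
#' @param seed RNG seed.
#' @param samples optional sample index (defaults to ingroup).
#' @param correction sampling-floor convention as in [ne_unlinked()].
#' @return A `data.frame` per retained bin: `c_low`, `c_high`, `c_mid`
#'   (geometric midpoint), `t`, `ne`, `mean_r2`, `n_pairs`.
#' @export
ne_trajectory <- function(vt, rec = recombination_model(), c_bins = NULL,
                          n_individuals = NULL, n_pairs_per_bin = 5000,
                          min_pairs = 50, seed = 1, samples = NULL,
                          correction = c("1/n", "1/(n-1)")) {
  correction <- match.arg(correction)
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  if (is.null(n_individuals)) n_individuals <- length(samples)
  if (is.null(c_bins))
    c_bins <- exp(seq(log(5e-4), log(0.05), length.out = 21))
  stopifnot(length(c_bins) >= 2, all(diff(c_bins) > 0))
  set.seed(seed)
  g <- vt$geno[, samples, drop = FALSE]
  floor_ <- .r2_floor(n_individuals, correction)
  # Morgans -> bp under the constant-rate map
  bp_edges <- c_bins * 100 / rec$rate * 1e6
  chroms <- unique(vt$chrom)
  rows <- list()
  for (b in seq_len(length(c_bins) - 1L)) {
    lo <- bp_edges[b]; hi <- bp_edges[b + 1L]
    ii <- integer(0); jj <- integer(0)
    for (attempt in 1:4) {
      need <- n_pairs_per_bin - length(ii)
      if (need <= 0) break
      anch <- sample.int(n_sites(vt), 2 * need, replace = TRUE)
      for (cc in chroms) {
        m <- anch[vt$chrom[anch] == cc]
        if (!length(m)) next
        idx <- which(vt$chrom == cc)
        p <- vt$pos[idx]
        pa <- vt$pos[m]
        a_lo <- findInterval(pa + lo, p) + 1L       # first j: p[j] > pa+lo
        a_hi <- findInterval(pa + hi - 1e-9, p)     # last j: p[j] < pa+hi
        okm <- a_hi >= a_lo
        if (!any(okm)) next
        pick <- a_lo[okm] +
          floor(runif(sum(okm)) * (a_hi[okm] - a_lo[okm] + 1L))
        ii <- c(ii, m[okm]); jj <- c(jj, idx[pick])
      }
    }
    if (length(ii) > n_pairs_per_bin) {
      ii <- ii[seq_len(n_pairs_per_bin)]; jj <- jj[seq_len(n_pairs_per_bin)]
    }
    if (length(ii) < min_pairs) {
      message(sprintf("ne_trajectory: bin %d dropped (%d pairs)",
                      b, length(ii)))
      next
    }
    r2v <- .pair_r2(g, ii, jj)
    mr2 <- mean(r2v, na.rm = TRUE)
    np <- sum(!is.na(r2v))
    c_mid <- sqrt(c_bins[b] * c_bins[b + 1L])
    drift <- mr2 - floor_
    if (!is.finite(drift) || drift <= 0 || np < min_pairs) {
      message(sprintf("ne_trajectory: bin %d dropped (drift residual <= 0)",
                      b))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      c_low = c_bins[b], c_high = c_bins[b + 1L], c_mid = c_mid,
      t = 1 / (2 * c_mid), ne = (1 / drift - 1) / (4 * c_mid),
      mean_r2 = mr2, n_pairs = np)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(c_low = numeric(), c_high = numeric(),
                         c_mid = numeric(), t = numeric(), ne = numeric(),
                         mean_r2 = numeric(), n_pairs = integer())
  rownames(out) <- NULL
  out
}
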