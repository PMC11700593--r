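#' Site-filter configuration
#'
#' Defaults mirror the standard VCFtools-style hard filters for biallelic
#' SNP datasets: `--maf 0.05 --max-missing 0.9 --minQ 30 --minDP 5
#' --min-meanDP 5`.  `max_missing` follows the usual semantics of that
#' flag: the *minimum fraction of present calls* a site must reach.
#'
#' @param biallelic_only drop records with more than one alternate allele.
#' @param maf_min minimum minor-allele frequency, computed on non-missing
#'   alleles only; in `[0, 0.5]`.
#' @param max_missing minimum fraction of non-missing genotypes; in `[0,1]`.
#' @param min_qual minimum site QUAL (skipped when QUAL is absent).
#' @param min_dp per-call depth below which a genotype is masked to missing
#'   *before* the missingness test (skipped when depths are absent).
#' @param min_mean_dp minimum mean depth across calls at a site.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(biallelic_only = TRUE, maf_min = 0.05,
                          max_missing = 0.9, min_qual = 30,
                          min_dp = 5, min_mean_dp = 5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  structure(list(biallelic_only = biallelic_only, maf_min = maf_min,
                 max_missing = max_missing, min_qual = min_qual,
                 min_dp = min_dp, min_mean_dp = min_mean_dp),
            class = "filter_config")
}

#' Apply hard site filters
#'
#' Filters are applied in a fixed order: low-depth calls are masked to
#' missing, then sites failing (in sequence) the biallelic, QUAL,
#' mean-depth, missingness and MAF criteria are removed; the report
#' attributes each removed site to the first criterion it failed.  Only
#' ingroup samples (population label != `"OUT"`) enter the missingness and
#' MAF computations.  Applying the same configuration twice removes nothing
#' on the second pass.
#'
#' @param vt a [variant_table()].
#' @param cfg a [filter_config()].
#' @return A list with elements `variants` (the filtered table) and
#'   `report` (a `data.frame` of `criterion`, `removed` counts; the
#'   `low_dp_calls_masked` row counts masked *calls*, not sites).
#' @export
apply_site_filters <- function(vt, cfg = filter_config()) {
  report <- list()
  if (n_sites(vt) == 0) {
    warning("empty variant table: nothing to filter")
    return(list(variants = vt,
                report = data.frame(criterion = character(),
                                    removed = integer())))
  }
  ing <- ingroup_samples(vt)
  # mask low-depth calls first (affects missingness and MAF below)
  masked <- 0L
  if (!is.null(vt$depth) && !is.null(cfg$min_dp)) {
    low <- !is.na(vt$depth) & vt$depth < cfg$min_dp & !is.na(vt$geno)
    masked <- sum(low)
    vt$geno[low] <- NA_integer_
  }
  report$low_dp_calls_masked <- masked

  keep <- rep(TRUE, n_sites(vt))
  drop_as <- function(fail, name) {
    fail <- fail & keep
    report[[name]] <<- sum(fail)
    keep <<- keep & !fail
  }
  if (isTRUE(cfg$biallelic_only))
    drop_as(vt$multiallelic | is.na(vt$alt), "not_biallelic")
  if (!is.null(vt$qual) && !is.null(cfg$min_qual))
    drop_as(!is.na(vt$qual) & vt$qual < cfg$min_qual, "qual")
  if (!is.null(vt$depth) && !is.null(cfg$min_mean_dp)) {
    mdp <- rowMeans(vt$depth, na.rm = TRUE)
    drop_as(!is.nan(mdp) & mdp < cfg$min_mean_dp, "mean_depth")
  }
  g <- vt$geno[, ing, drop = FALSE]
  present <- rowMeans(!is.na(g))
  drop_as(present < cfg$max_missing, "missingness")
  drop_as(site_maf(vt) < cfg$maf_min, "maf")

  out <- subset_variants(vt, sites = which(keep))
  if (!is.null(vt$annotation)) out$annotation <- vt$annotation[which(keep), ]
  list(variants = out,
       report = data.frame(criterion = names(report),
                           removed = unlist(report, use.names = FALSE)))
}

#' Minor-allele frequency per site
#'
#' Computed on non-missing ingroup alleles only; sites with no calls get
#' `NaN`.
#'
#' @param vt a [variant_table()].
#' @return numeric vector of per-site MAF in `[0, 0.5]`.
#' @export
site_maf <- function(vt) {
  g <- vt$geno[, ingroup_samples(vt), drop = FALSE]
  ac <- rowSums(g, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(g))
  f <- ac / an
  pmin(f, 1 - f)
}

#' Squared genotype correlation between two sites
#'
#' Squared Pearson correlation of alt-allele dosages over pairwise-complete
#' samples; the LD measure used for pruning and Ne estimation.
#'
#' @param vt a [variant_table()].
#' @param site_a,site_b site indices.
#' @param samples optional sample index (defaults to ingroup).
#' @return r^2 in `[0,1]`, or `NA` when fewer than 2 complete pairs remain
#'   or either site is monomorphic among them.
#' @export
r2 <- function(vt, site_a, site_b, samples = NULL) {
  if (is.null(samples)) samples <- ingroup_samples(vt)
  x <- vt$geno[site_a, samples]
  y <- vt$geno[site_b, samples]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(.undefined)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(.undefined)
  cor(x, y)^2
}

#' LD-pruning configuration
#'
#' Defaults follow the common `--indep-pairwise 10 5 0.5` idiom: a 10 kb
#' window and an r^2 ceiling of 0.5.  `step_sites` is accepted for
#' interface compatibility but the pruning result is step-independent: the
#' implementation removes violating pairs globally so that *no* retained
#' same-chromosome pair closer than `window_kb` exceeds `r2_max` (a
#' strictly stronger guarantee than a stepped scan; see the methods
#' vignette).
#'
#' @param window_kb pair-comparison window in kb.
#' @param step_sites nominal scan step (sites); retained for compatibility.
#' @param r2_max maximum tolerated r^2 inside a window.
#' @return A list of class `ld_prune_config`.
#' @export
ld_prune_config <- function(window_kb = 10, step_sites = 5, r2_max = 0.5) {
  stopifnot(window_kb > 0, step_sites > 0, r2_max > 0)
  structure(list(window_kb = window_kb, step_sites = step_sites,
                 r2_max = r2_max), class = "ld_prune_config")
}

#' Prune sites in linkage disequilibrium
#'
#' Deterministic greedy pruning: all same-chromosome site pairs closer than
#' `window_kb` are examined in decreasing r^2 order; while a pair with both
#' members retained exceeds `r2_max`, the member with the smaller MAF is
#' removed (ties: the larger position).  After pruning, an exhaustive scan
#' of retained pairs within the window finds no violation.
#'
#' @param vt a [variant_table()].
#' @param cfg an [ld_prune_config()].
#' @return Sorted integer vector of retained site indices.
#' @export
ld_prune <- function(vt, cfg = ld_prune_config()) {
  S <- n_sites(vt)
  if (S == 0) return(integer())
  win <- cfg$window_kb * 1000
  maf <- site_maf(vt)
  pr <- .window_pairs(vt, win)
  if (nrow(pr) == 0) return(seq_len(S))
  r2v <- vapply(seq_len(nrow(pr)),
                function(k) r2(vt, pr$i[k], pr$j[k]), 0)
  viol <- which(!is.na(r2v) & r2v > cfg$r2_max)
  keep <- rep(TRUE, S)
  for (k in viol[order(-r2v[viol], pr$i[viol], pr$j[viol])]) {
    i <- pr$i[k]; j <- pr$j[k]
    if (!keep[i] || !keep[j]) next
    victim <- if (is.na(maf[i]) || is.na(maf[j])) max(i, j)
      else if (maf[i] < maf[j]) i
      else if (maf[j] < maf[i]) j
      else if (vt$pos[i] >= vt$pos[j]) i else j
    keep[victim] <- FALSE
  }
  which(keep)
}

# all same-chromosome index pairs with pos_j - pos_i < win (i < j)
.window_pairs <- function(vt, win) {
  ii <- integer(); jj <- integer()
  for (cc in unique(vt$chrom)) {
    idx <- which(vt$chrom == cc)
    p <- vt$pos[idx]
    hi <- findInterval(p + win - 1e-9, p)  # last j with p[j] < p[i] + win
    for (a in seq_along(idx)) {
      if (hi[a] > a) {
        ii <- c(ii, rep(idx[a], hi[a] - a))
        jj <- c(jj, idx[(a + 1):hi[a]])
      }
    }
  }
  data.frame(i = ii, j = jj)
}
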