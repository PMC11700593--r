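#' Polarize ancestral vs derived alleles with up to two outgroups
#'
#' Rule-based polarization: when both outgroup calls agree on an allele
#' that matches the ingroup ref or alt, that allele is ancestral
#' (`agreeing_outgroups`); when only one outgroup carries a usable allele,
#' it decides (`single_outgroup`); when the two usable outgroup alleles
#' disagree (one ref, one alt), a seeded random pick breaks the tie
#' (`tie_random`); when no outgroup allele matches ref or alt the site is
#' `unresolved` and is dropped from load accounting downstream.
#'
#' @param vt a [variant_table()].
#' @param outgroup_bases character matrix, sites x 2 (or x 1), of outgroup
#'   allele calls (`NA` for no data); see [outgroup_alleles()] for
#'   simulated data.
#' @param seed seed for the tie-breaking draws (one uniform draw is
#'   consumed per site, so the tie pattern does not shift other sites'
#'   picks).
#' @return A `data.frame` per site: `ancestral`, `derived` (both `NA` when
#'   unresolved), `confidence` in
#'   `{agreeing_outgroups, single_outgroup, tie_random, unresolved}`.
#' @export
polarize <- function(vt, outgroup_bases, seed = 1) {
  ob <- as.matrix(outgroup_bases)
  stopifnot(nrow(ob) == n_sites(vt), ncol(ob) %in% 1:2)
  if (ncol(ob) == 1) ob <- cbind(ob, NA_character_)
  set.seed(seed)
  u <- runif(n_sites(vt))
  use1 <- !is.na(ob[, 1]) & (ob[, 1] == vt$ref | ob[, 1] == vt$alt)
  use2 <- !is.na(ob[, 2]) & (ob[, 2] == vt$ref | ob[, 2] == vt$alt)
  anc <- rep(NA_character_, n_sites(vt))
  conf <- rep("unresolved", n_sites(vt))
  both <- use1 & use2
  agree <- both & ob[, 1] == ob[, 2]
  anc[agree] <- ob[agree, 1]
  conf[agree] <- "agreeing_outgroups"
  tie <- both & ob[, 1] != ob[, 2]
  anc[tie] <- ifelse(u[tie] < 0.5, vt$ref[tie], vt$alt[tie])
  conf[tie] <- "tie_random"
  one <- xor(use1, use2)
  anc[one] <- ifelse(use1[one], ob[one, 1], ob[one, 2])
  conf[one] <- "single_outgroup"
  der <- ifelse(is.na(anc), NA_character_,
                ifelse(anc == vt$ref, vt$alt, vt$ref))
  data.frame(ancestral = anc, derived = der, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Retain sites whose derived state is the alternate allele
#'
#' After this orientation step the dosage of a retained site directly
#' counts derived-allele copies, which is what the load tabulation
#' assumes.  Sites whose derived allele is the reference, and unresolved
#' sites, are dropped and counted.
#'
#' @param pol output of [polarize()].
#' @param vt the matching [variant_table()].
#' @return A list: `keep` (integer site indices) and `report`
#'   (`data.frame` of `status` in
#'   `{retained, derived_is_ref, unresolved}` and `n`).
#' @export
orient_derived <- function(pol, vt) {
  stopifnot(nrow(pol) == n_sites(vt))
  status <- ifelse(is.na(pol$derived), "unresolved",
                   ifelse(pol$derived == vt$alt, "retained",
                          "derived_is_ref"))
  list(keep = which(status == "retained"),
       report = data.frame(
         status = c("retained", "derived_is_ref", "unresolved"),
         n = c(sum(status == "retained"), sum(status == "derived_is_ref"),
               sum(status == "unresolved"))))
}

#' Classify variant impact into load categories
#'
#' `LOW` and `HIGH` map to themselves (SIFT is ignored there); `MODERATE`
#' splits on the SIFT score into tolerated (`MOD-TOL`, score >= 0.05) and
#' putatively deleterious (`MOD-DEL`, score < 0.05); `MODERATE` without a
#' score, and any other impact string, are excluded (`NA`).
#'
#' @param annotation `data.frame` with columns `impact` and `sift_score`
#'   (e.g. the `annotation` field of [read_vcf()] or
#'   [sim_annotations()]).
#' @return Character vector over
#'   `{LOW, MOD-TOL, MOD-DEL, HIGH, NA}` with an `excluded` attribute
#'   counting `MODERATE`-without-SIFT and other-impact sites.
#' @export
classify_impact <- function(annotation) {
  imp <- toupper(as.character(annotation$impact))
  sift <- as.numeric(annotation$sift_score)
  out <- rep(NA_character_, length(imp))
  out[imp == "LOW"] <- "LOW"
  out[imp == "HIGH"] <- "HIGH"
  mod <- !is.na(imp) & imp == "MODERATE"
  out[mod & !is.na(sift) & sift >= 0.05] <- "MOD-TOL"
  out[mod & !is.na(sift) & sift < 0.05] <- "MOD-DEL"
  attr(out, "excluded") <- c(moderate_no_sift = sum(mod & is.na(sift)),
                             other_impact = sum(is.na(out)) -
                               sum(mod & is.na(sift)))
  out
}

#' Per-individual masked / realized / total load counts
#'
#' Over derived-oriented sites of each category: `masked` counts
#' heterozygous genotypes (dosage 1, the load hidden from selection in
#' partially recessive variants), `realized` counts derived homozygotes
#' (dosage 2, the load expressed now), `total = masked + realized`, and
#' `derived_freq = (masked + 2 realized) / (2 callable)` with `callable`
#' the category's non-missing calls of that individual.  Missing calls are
#' excluded from numerator and denominator.
#'
#' @param vt a [variant_table()] whose retained sites are derived-oriented
#'   (see [orient_derived()]).
#' @param categories per-site category vector from [classify_impact()]
#'   (length `n_sites(vt)`; `NA` sites are ignored).
#' @param keep optional site indices to restrict to (e.g. the `keep` of
#'   [orient_derived()]).
#' @param samples optional sample index (defaults to ingroup).
#' @return A `data.frame`: `sample`, `category`, `masked`, `realized`,
#'   `total`, `callable`, `derived_freq` (`NA` when a category has no
#'   callable site).
#' @export
load_counts <- function(vt, categories, keep = NULL, samples = NULL) {
  stopifnot(length(categories) == n_sites(vt))
  if (is.null(samples)) samples <- ingroup_samples(vt)
  if (is.character(samples)) samples <- match(samples, vt$samples)
  if (is.null(keep)) keep <- seq_len(n_sites(vt))
  cats <- c("LOW", "MOD-TOL", "MOD-DEL", "HIGH")
  rows <- list()
  for (cat in cats) {
    idx <- keep[!is.na(categories[keep]) & categories[keep] == cat]
    g <- vt$geno[idx, samples, drop = FALSE]
    masked <- colSums(g == 1L, na.rm = TRUE)
    realized <- colSums(g == 2L, na.rm = TRUE)
    callable <- colSums(!is.na(g))
    rows[[cat]] <- data.frame(
      sample = vt$samples[samples], category = cat,
      masked = as.integer(masked), realized = as.integer(realized),
      total = as.integer(masked + realized),
      callable = as.integer(callable),
      derived_freq = ifelse(callable > 0,
                            (masked + 2 * realized) / (2 * callable),
                            NA_real_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact two-tailed Mann-Whitney rank test
#'
#' Full enumeration of all `choose(n1+n2, n1)` assignments of the observed
#' (midrank-tied) values to the two groups; the two-tailed p-value is the
#' fraction of assignments whose U statistic deviates from its mean
#' `n1 n2 / 2` at least as much as the observed one.  Intended for the
#' small-sample regime (2 to 20 per group); enumeration beyond 2e6
#' combinations errors, directing to a normal approximation (out of
#' scope).
#'
#' @param values_a,values_b numeric group samples.
#' @return A list: `p` (exact two-tailed p), `U` (observed statistic for
#'   group a), `n_combinations`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
compare_groups <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  stopifnot(n1 >= 2, n2 >= 2, n1 <= 20, n2 <= 20)
  ncomb <- choose(n1 + n2, n1)
  if (ncomb > 2e6)
    stop("exact enumeration over ", format(ncomb, big.mark = ","),
         " assignments exceeds the cap; use a normal approximation")
  r <- rank(c(values_a, values_b))  # midranks for ties
  off <- n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - off
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combs], nrow = n1)) - off
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(p = p, U = u_obs, n_combinations = ncomb)
}
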