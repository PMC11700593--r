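#' Simulation configuration
#'
#' Defaults describe a desk-scale stand-in for a bottlenecked wolf-like
#' population: a 4 x 20 Mb genome at the canid average recombination rate,
#' an ancestral size of 100 diploids collapsing to 25 between 18 and 12
#' generations before present and recovering to 30 afterwards, and a
#' per-bp mutation rate inflated (relative to a real vertebrate rate) so
#' the small genome still yields on the order of 50k segregating sites.
#' See the methods vignette for how each default was chosen and what the
#' desk scaling does and does not preserve.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (all equal).
#' @param mu per-bp per-generation mutation rate.
#' @param rec_rate recombination rate, cM/Mb.
#' @param ne_trajectory `data.frame(start, end, N)`: diploid size per
#'   epoch in generations before present, most-recent first, covering
#'   `[0, Inf)` without gaps (`end` of the last row must be `Inf`).
#' @param bottleneck optional `c(start, end, N)` (generations before
#'   present, `start < end`) spliced over the trajectory.
#' @param sample_size diploid individuals emitted (before pedigree
#'   offspring and outgroups are appended).
#' @param class_probs probabilities over
#'   `c(NEUTRAL, LOW, MODERATE, HIGH)`; must sum to 1.
#' @param sift_mixture `list(p_del = ...)`: probability that a MODERATE
#'   site's SIFT score falls below 0.05 (scores are uniform within the
#'   chosen side of the threshold).
#' @param sel_coeffs selection model: `list(MODERATE = c(shape, mean),
#'   HIGH = c(shape, mean), h = dominance)`; selection coefficients are
#'   gamma-distributed per site, LOW and NEUTRAL are neutral.
#' @param outgroup_divergence generations separating each outgroup lineage
#'   from the ingroup ancestor (drives the outgroup mismatch rate
#'   `1 - exp(-mu * divergence)`).
#' @param n_pedigree_pairs parent-offspring pairs appended with recorded
#'   truth.
#' @param mean_depth mean of the Poisson per-call depth emitted as DP.
#' @param burn_in generations run at the ancestral size before the epochs
#'   start; default `min(2 * N_ancestral, 150)`.
#' @param seed RNG seed; the seed fully determines the output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4, chrom_length = 2e7, mu = 2.5e-7,
                       rec_rate = 1.3459,
                       ne_trajectory = data.frame(
                         start = c(0, 12, 18), end = c(12, 18, Inf),
                         N = c(30, 25, 100)),
                       bottleneck = NULL, sample_size = 12,
                       class_probs = c(NEUTRAL = 0.85, LOW = 0.08,
                                       MODERATE = 0.05, HIGH = 0.02),
                       sift_mixture = list(p_del = 0.4),
                       sel_coeffs = list(MODERATE = c(shape = 0.2,
                                                      mean = 0.02),
                                         HIGH = c(shape = 0.2, mean = 0.08),
                                         h = 0.2),
                       outgroup_divergence = 1e5, n_pedigree_pairs = 1,
                       mean_depth = 20, burn_in = NULL, seed = 1) {
  if (!is.null(bottleneck)) {
    stopifnot(length(bottleneck) == 3, bottleneck[1] < bottleneck[2])
    ne_trajectory <- .splice_bottleneck(ne_trajectory, bottleneck)
  }
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, mu = mu, rec_rate = rec_rate,
    ne_trajectory = ne_trajectory, sample_size = as.integer(sample_size),
    class_probs = class_probs, sift_mixture = sift_mixture,
    sel_coeffs = sel_coeffs, outgroup_divergence = outgroup_divergence,
    n_pedigree_pairs = as.integer(n_pedigree_pairs),
    mean_depth = mean_depth, burn_in = burn_in, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tr <- cfg$ne_trajectory
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0, cfg$mu >= 0,
            cfg$rec_rate >= 0, cfg$sample_size >= 1,
            cfg$outgroup_divergence >= 0, cfg$n_pedigree_pairs >= 0)
  if (any(tr$N <= 0))
    stop("configuration error: non-positive population size in an epoch")
  if (tr$start[1] != 0 || !is.infinite(tr$end[nrow(tr)]))
    stop("ne_trajectory must cover [0, Inf) most-recent first")
  if (nrow(tr) > 1 && any(tr$start[-1] != tr$end[-nrow(tr)]))
    stop("ne_trajectory epochs must be contiguous and non-overlapping")
  if (abs(sum(cfg$class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1")
  if (!identical(names(cfg$class_probs),
                 c("NEUTRAL", "LOW", "MODERATE", "HIGH")))
    stop("class_probs must be named NEUTRAL, LOW, MODERATE, HIGH")
  invisible(cfg)
}

.splice_bottleneck <- function(tr, bn) {
  s <- bn[1]; e <- bn[2]; nb <- bn[3]
  pieces <- list()
  for (k in seq_len(nrow(tr))) {
    a <- tr$start[k]; b <- tr$end[k]; n <- tr$N[k]
    if (b <= s || a >= e) { pieces[[length(pieces) + 1]] <- c(a, b, n); next }
    if (a < s) pieces[[length(pieces) + 1]] <- c(a, s, n)
    if (b > e) pieces[[length(pieces) + 1]] <- c(e, b, n)
  }
  pieces[[length(pieces) + 1]] <- c(s, e, nb)
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2], N = m[, 3])
}

#' Simulate a bottlenecked population with recombination and selection
#'
#' Forward-in-time diploid Wright-Fisher simulation: standing variation is
#' initialized at mutation-drift equilibrium (neutral folded-spectrum
#' frequencies), the population is burned in at the ancestral size, then
#' driven through the configured epochs to the present.  Each generation
#' applies viability selection (dominance `h`, gamma-distributed `s` for
#' MODERATE/HIGH sites), random mating with Poisson crossovers at
#' `rec_rate`, and new mutations.  The emitted [variant_table()] holds the
#' requested samples, any pedigree offspring, and two outgroup columns
#' (population `"OUT"`); sites monomorphic across the emitted ingroup are
#' excluded.  The companion truth record carries everything needed for
#' parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_result`: `variants` (a `variant_table`)
#'   and `truth` (a list: `ancestral` per-site ancestral base, `class`
#'   per-site variant class, `sift`, `s`, `h`, `outgroup_bases` (sites x
#'   2), `pedigree` (`data.frame(parent, offspring)`), `outgroup_samples`,
#'   `ne_trajectory`, `config`).  Identical configs (including the seed)
#'   produce identical results.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  L <- config$chrom_length
  L_tot <- config$n_chromosomes * L
  tr <- config$ne_trajectory
  n_anc <- tr$N[nrow(tr)]
  burn <- config$burn_in %||% min(2 * n_anc, 150)
  # forward plan: burn-in at ancestral N, then epochs old -> recent
  fin <- tr[is.finite(tr$end), , drop = FALSE]
  plan_n <- c(rep(n_anc, burn),
              if (nrow(fin)) rep(rev(fin$N), rev(fin$end - fin$start)))
  st <- .sim_init(config, n_anc)
  for (gen in seq_along(plan_n))
    st <- .sim_generation(st, as.integer(plan_n[gen]), config)
  .sim_emit(st, config)
}

# initial standing variation at mutation-drift(-selection) equilibrium:
# neutral sites get the 1/i frequency spectrum; selected sites are
# down-weighted by the stationary-density factor exp(-4 N h s p), so
# deleterious variants start rare instead of at neutral frequencies
# (otherwise the burn-in opens with an absurd purge and a fitness-variance
# crash of Ne)
.sim_init <- function(cfg, n0) {
  nh <- 2L * n0
  theta <- 4 * n0 * cfg$mu * cfg$n_chromosomes * cfg$chrom_length
  a_n <- sum(1 / seq_len(nh - 1L))
  s0 <- max(1L, rpois(1, theta * a_n))
  meta <- .new_site_meta(s0, cfg)
  copies <- seq_len(nh - 1L)
  w_neutral <- 1 / copies
  i <- integer(s0)
  neu <- meta$s == 0
  i[neu] <- sample.int(nh - 1L, sum(neu), replace = TRUE,
                       prob = w_neutral)
  h <- cfg$sel_coeffs$h
  for (k in which(!neu)) {
    w <- w_neutral * exp(-4 * n0 * h * meta$s[k] * copies / nh)
    i[k] <- sample.int(nh - 1L, 1L, prob = w)
  }
  H <- matrix(0L, s0, nh)
  for (k in seq_len(s0)) H[k, sample.int(nh, i[k])] <- 1L
  o <- order(meta$chrom, meta$pos)
  list(H = H[o, , drop = FALSE], meta = lapply(meta, `[`, o))
}

# draw chrom/pos/class/s/sift for n new sites
.new_site_meta <- function(n, cfg) {
  cls <- sample.int(4L, n, replace = TRUE, prob = cfg$class_probs)
  s <- numeric(n)
  for (k in c(3L, 4L)) {
    nm <- c("NEUTRAL", "LOW", "MODERATE", "HIGH")[k]
    m <- cls == k
    if (any(m)) {
      par <- cfg$sel_coeffs[[nm]]
      # cap below 1 so a derived homozygote keeps finite log-fitness
      s[m] <- pmin(0.99, rgamma(sum(m), shape = par[["shape"]],
                                scale = par[["mean"]] / par[["shape"]]))
    }
  }
  sift <- rep(NA_real_, n)
  mod <- cls == 3L
  if (any(mod)) {
    del <- runif(sum(mod)) < cfg$sift_mixture$p_del
    sift[mod] <- ifelse(del, runif(sum(mod), 0, 0.05),
                        runif(sum(mod), 0.05, 1))
  }
  list(chrom = sample.int(cfg$n_chromosomes, n, replace = TRUE),
       pos = runif(n, 0, cfg$chrom_length),
       class = cls, s = s, sift = sift)
}

.sim_fitness <- function(H, meta, h) {
  n <- ncol(H) / 2L
  sel <- which(meta$s > 0)
  if (!length(sel)) return(rep(1, n))
  dos <- H[sel, 2 * seq_len(n) - 1L, drop = FALSE] +
         H[sel, 2 * seq_len(n), drop = FALSE]
  lw <- colSums((dos == 1L) * log1p(-h * meta$s[sel])) +
        colSums((dos == 2L) * log1p(-meta$s[sel]))
  exp(lw - max(lw))
}

# one Wright-Fisher generation: selection, mating, recombination, mutation
.sim_generation <- function(st, n_next, cfg) {
  H <- st$H; meta <- st$meta
  n_par <- ncol(H) / 2L
  w <- .sim_fitness(H, meta, cfg$sel_coeffs$h)
  pa <- sample.int(n_par, n_next, replace = TRUE, prob = w)
  pb <- sample.int(n_par, n_next, replace = TRUE, prob = w)
  while (any(same <- pa == pb) && n_par > 1)
    pb[same] <- sample.int(n_par, sum(same), replace = TRUE, prob = w)
  parent <- integer(2L * n_next)
  parent[2L * seq_len(n_next) - 1L] <- pa
  parent[2L * seq_len(n_next)] <- pb
  xo <- .draw_crossovers(2L * n_next, cfg)
  Hc <- wf_gametes(H, st$meta$chrom, st$meta$pos, parent, xo$breaks,
                   xo$starts)
  # new mutations
  nm <- rpois(2L * n_next, cfg$mu * cfg$n_chromosomes * cfg$chrom_length)
  tot <- sum(nm)
  if (tot > 0) {
    newm <- .new_site_meta(tot, cfg)
    block <- matrix(0L, tot, 2L * n_next)
    block[cbind(seq_len(tot), rep(seq_along(nm), nm))] <- 1L
    Hc <- rbind(Hc, block)
    meta <- Map(c, meta, newm)
  }
  rs <- rowSums(Hc)
  keep <- which(rs > 0L & rs < ncol(Hc))
  Hc <- Hc[keep, , drop = FALSE]
  meta <- lapply(meta, `[`, keep)
  o <- order(meta$chrom, meta$pos)
  list(H = Hc[o, , drop = FALSE], meta = lapply(meta, `[`, o))
}

.draw_crossovers <- function(n_gam, cfg) {
  morgans <- cfg$chrom_length / 1e6 * cfg$rec_rate / 100
  nx <- matrix(rpois(n_gam * cfg$n_chromosomes, morgans),
               nrow = cfg$n_chromosomes)
  breaks <- lapply(seq_len(n_gam), function(g)
    lapply(seq_len(cfg$n_chromosomes), function(cc)
      sort(runif(nx[cc, g], 0, cfg$chrom_length))))
  starts <- matrix(sample(0:1, n_gam * cfg$n_chromosomes, replace = TRUE),
                   nrow = cfg$n_chromosomes)
  list(breaks = breaks, starts = starts)
}

# single gamete in R (used for pedigree offspring at emission time)
.one_gamete <- function(H, meta, ind, cfg) {
  xo <- .draw_crossovers(1L, cfg)
  as.integer(wf_gametes(H, meta$chrom, meta$pos, ind, xo$breaks,
                        xo$starts))
}

.sim_emit <- function(st, cfg) {
  H <- st$H; meta <- st$meta
  n_fin <- ncol(H) / 2L
  n_out <- min(cfg$sample_size, n_fin)
  if (n_out < cfg$sample_size)
    warning("final population smaller than sample_size; emitting ", n_out)
  ids <- sprintf("ind_%02d", seq_len(n_out))
  cols <- as.vector(rbind(2L * seq_len(n_out) - 1L, 2L * seq_len(n_out)))
  Hs <- H[, cols, drop = FALSE]
  # pedigree offspring: parent = emitted individual k, mate random other
  ped <- data.frame(parent = character(), offspring = character())
  for (k in seq_len(min(cfg$n_pedigree_pairs, n_out))) {
    mate <- sample(setdiff(seq_len(n_fin), k), 1)
    g1 <- .one_gamete(H, meta, k, cfg)
    g2 <- .one_gamete(H, meta, mate, cfg)
    Hs <- cbind(Hs, g1, g2)
    off <- sprintf("ped_off_%02d", k)
    ids <- c(ids, off)
    ped <- rbind(ped, data.frame(parent = sprintf("ind_%02d", k),
                                 offspring = off))
  }
  n_em <- length(ids)
  D <- Hs[, 2 * seq_len(n_em) - 1L, drop = FALSE] +
       Hs[, 2 * seq_len(n_em), drop = FALSE]
  # keep sites polymorphic among emitted ingroup individuals
  ds <- rowSums(D)
  keep <- which(ds > 0L & ds < 2L * n_em)
  D <- D[keep, , drop = FALSE]
  meta <- lapply(meta, `[`, keep)
  S <- length(keep)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, S, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), "")
  # outgroup lineages: ancestral base unless mutated since divergence
  p_mis <- 1 - exp(-cfg$mu * cfg$outgroup_divergence)
  og <- matrix(anc, S, 2)
  for (k in 1:2) {
    mis <- runif(S) < p_mis
    if (any(mis))
      og[mis, k] <- vapply(anc[mis],
                           function(b) sample(setdiff(bases, b), 1), "")
  }
  # the reference genome is one random haplotype: ref = derived allele
  # with probability equal to the derived sample frequency
  p_der <- rowSums(D) / (2 * n_em)
  flip <- runif(S) < p_der
  ref <- ifelse(flip, der, anc)
  alt <- ifelse(flip, anc, der)
  geno <- D
  geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  # outgroups emitted as homozygous diploid columns where codable
  og_dos <- matrix(NA_integer_, S, 2)
  for (k in 1:2)
    og_dos[, k] <- ifelse(og[, k] == ref, 0L,
                          ifelse(og[, k] == alt, 2L, NA_integer_))
  out_ids <- c("outgroup_1", "outgroup_2")
  geno <- cbind(geno, og_dos)
  colnames(geno) <- c(ids, out_ids)
  depth <- matrix(rpois(length(geno), cfg$mean_depth), nrow = S)
  qual <- round(runif(S, 35, 60), 1)
  vt <- variant_table(
    chrom = paste0("chr", meta$chrom),
    pos = .unique_int_pos(meta$chrom, meta$pos),
    ref = ref, alt = alt, geno = geno, qual = qual, depth = depth,
    samples = c(ids, out_ids),
    populations = c(rep("POP", n_em), rep("OUT", 2)))
  cls_names <- c("NEUTRAL", "LOW", "MODERATE", "HIGH")
  truth <- list(
    ancestral = anc, class = cls_names[meta$class], sift = meta$sift,
    s = meta$s, h = cfg$sel_coeffs$h, outgroup_bases = og,
    pedigree = ped, outgroup_samples = out_ids,
    ne_trajectory = cfg$ne_trajectory, config = cfg)
  structure(list(variants = vt, truth = truth), class = "sim_result")
}

# continuous positions -> strictly increasing integers per chromosome
.unique_int_pos <- function(chrom, pos) {
  p <- as.integer(floor(pos)) + 1L
  for (cc in unique(chrom)) {
    m <- which(chrom == cc)
    i <- seq_along(m)
    p[m] <- cummax(p[m] - i) + i
  }
  p
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>\n")
  print(x$variants)
  cat(sprintf("  pedigree pairs: %d; outgroups: %s\n",
              nrow(x$truth$pedigree),
              paste(x$truth$outgroup_samples, collapse = ", ")))
  invisible(x)
}

#' Outgroup allele calls of a simulation
#'
#' @param sim a `sim_result` from [simulate_population()].
#' @return Character matrix, sites x 2, of outgroup bases (suitable for
#'   [polarize()]).
#' @export
outgroup_alleles <- function(sim) sim$truth$outgroup_bases

#' Per-site annotation table of a simulation
#'
#' Formats the truth channel the way an effect-prediction pipeline would:
#' impact strings (`MODIFIER` for neutral sites, otherwise the class) and
#' SIFT scores for MODERATE sites.
#'
#' @param sim a `sim_result`.
#' @return A `data.table` with `chrom, pos, impact, sift_score`.
#' @export
sim_annotations <- function(sim) {
  imp <- sim$truth$class
  imp[imp == "NEUTRAL"] <- "MODIFIER"
  data.table::data.table(chrom = sim$variants$chrom,
                         pos = sim$variants$pos, impact = imp,
                         sift_score = sim$truth$sift)
}

#' Write a simulation to disk
#'
#' Emits `sim.vcf` (GT + DP, contig headers from the configuration),
#' `annotations.tsv` (sidecar impact/SIFT table) and `truth.json`.
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- rep(sim$truth$config$chrom_length,
            sim$truth$config$n_chromosomes)
  names(cl) <- paste0("chr", seq_len(sim$truth$config$n_chromosomes))
  write_vcf(sim$variants, file.path(dir, "sim.vcf"), chrom_lengths = cl)
  data.table::fwrite(sim_annotations(sim),
                     file.path(dir, "annotations.tsv"), sep = "\t")
  tr <- sim$truth
  jsonlite::write_json(list(
    ancestral = tr$ancestral, class = tr$class, sift = tr$sift, s = tr$s,
    h = tr$h, outgroup_bases = tr$outgroup_bases, pedigree = tr$pedigree,
    outgroup_samples = tr$outgroup_samples,
    ne_trajectory = tr$ne_trajectory),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
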