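#' Empirical insert-size distribution
#'
#' Builds a resampling-ready empirical distribution of insert sizes from an
#' informative-pairs table (or file), so that simulated read pairs match
#' the insert-size profile of a real dataset.
#'
#' @param pairs Informative-pairs `data.frame`, a path to a pairs TSV, or a
#'   bare numeric vector of insert sizes.
#' @return An `insert_dist` object.
#' @export
sample_insert_distribution <- function(pairs) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  d <- if (is.numeric(pairs)) pairs else pairs$right_pos - pairs$left_pos
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) stop("no insert sizes to build a distribution from")
  structure(list(d = as.numeric(d)), class = "insert_dist")
}

#' Draw insert sizes from an empirical distribution
#'
#' @param dist An `insert_dist`.
#' @param n Number of draws.
#' @return Integer-valued insert sizes, resampled with replacement.
#' @export
draw_inserts <- function(dist, n) sample(dist$d, n, replace = TRUE)

#' Synthetic Hi-C insert sizes
#'
#' Draws insert sizes from a log-uniform distribution on
#' `[d_min, d_max]`, i.e. density proportional to `1/d` -- the canonical
#' power-law decay of Hi-C cis-contact distances. Used as a stand-in
#' insert-size source where no empirical pairs file is available; labelled
#' synthetic accordingly.
#'
#' @param n Number of draws.
#' @param d_min,d_max Insert range in bp (defaults 200 bp to 5 Mb).
#' @return Integer insert sizes.
#' @export
synthetic_insert_sizes <- function(n, d_min = 200, d_max = 5e6) {
  round(exp(runif(n, log(d_min), log(d_max))))
}

#' Piecewise-constant sawtooth reference map
#'
#' A deterministic test landscape alternating linearly between a trough
#' and a peak rate with the given period, emulating the orders-of-magnitude
#' rate variation of real chromosomes while staying fully known. The
#' default period of 7 Mb is deliberately long and incommensurate with the
#' usual evaluation bin widths, so that the truth has genuine variance at
#' every comparison scale from kilobases to several megabases.
#'
#' @param chrom_len Chromosome length in bp.
#' @param period Sawtooth period in bp (default 7 Mb).
#' @param lo,hi Trough/peak rates in cM/Mb (defaults 0.2 and 6).
#' @param n_steps Piecewise-constant steps per period (default 70).
#' @param chrom Chromosome name.
#' @return A `recomb_map` covering `[1, chrom_len)`.
#' @export
sawtooth_reference_map <- function(chrom_len, period = 7e6, lo = 0.2, hi = 6,
                                   n_steps = 70, chrom = "chrSim") {
  b <- unique(c(seq(1, chrom_len, by = period / n_steps), chrom_len))
  mid <- (b[-length(b)] + b[-1]) / 2
  phase <- (mid %% period) / period
  tri <- 1 - abs(2 * phase - 1)          # 0 at period edges, 1 mid-period
  rate <- (lo + (hi - lo) * tri) / 1e6   # cM/bp
  new_recomb_map(data.frame(chrom = chrom, start = b[-length(b)], end = b[-1],
                            rate = rate),
                 chrom, c(1, chrom_len))
}

#' Simulate crossover-informative read pairs from a reference map
#'
#' Each simulated pair receives an insert size drawn from `dist` and a left
#' endpoint uniform on `[1, L - d]`. Its true crossover status is Bernoulli
#' with probability given by the Haldane mapping function of the genetic
#' distance between its endpoints, `p = (1 - exp(-2 dM))/2` with `dM` in
#' Morgans from the reference map, which saturates correctly at 0.5 for
#' multi-Morgan inserts. The observed status is the true status flipped
#' with probability `error_rate` (symmetric false positives and false
#' negatives). Pairs carry near-zero base/phase error fields
#' (`b = p = 1e-6`) so the planted error rate is the only error source.
#' Pairs are generated until the mean effective coverage (total surveyed bp
#' divided by chromosome length) reaches `target_coverage`.
#'
#' Informative pairs are always bounded by phased heterozygous sites, so
#' simulated endpoints are snapped inward to a SNP grid drawn once per call
#' as a uniform random set with density `snp_density` (default 1 SNP/kb, a
#' typical outbred vertebrate heterozygosity). Pairs left without two
#' distinct bounding SNPs are discarded and replaced.
#'
#' @param ref Reference `recomb_map` covering the chromosome.
#' @param dist An `insert_dist` (see [sample_insert_distribution()] /
#'   [synthetic_insert_sizes()]).
#' @param target_coverage Target mean effective coverage (e.g. 1000).
#' @param error_rate Status flip probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param snp_density Phased heterozygous sites per bp (default 1e-3);
#'   `NULL` keeps the raw endpoints.
#' @param base_err,phase_err Error fields written on the simulated pairs.
#' @return Informative-pairs `data.frame` with attribute `truth` (logical
#'   vector of true crossover statuses) and `realized_coverage`.
#' @export
simulate_pairs <- function(ref, dist, target_coverage, error_rate = 0.01,
                           seed = NULL, snp_density = 1e-3,
                           base_err = 1e-6, phase_err = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- attr(ref, "chrom")
  L <- max(ref$end)
  snps <- if (is.null(snp_density)) NULL else
    sort(sample.int(L - 2L, size = max(2L, stats::rpois(1, snp_density * L))) + 1L)
  target_bp <- target_coverage * L
  mean_d <- mean(dist$d)
  d_all <- integer(0); l_all <- integer(0)
  while (sum(as.numeric(d_all)) < target_bp) {
    need <- max(100L, ceiling(1.05 * (target_bp - sum(as.numeric(d_all))) / mean_d))
    d <- draw_inserts(dist, need)
    d <- d[d < L - 1]
    l <- 1L + floor(runif(length(d)) * (L - d))
    if (!is.null(snps)) {
      r <- l + d
      li <- findInterval(l - 1L, snps) + 1L   # first SNP >= l
      ri <- findInterval(r, snps)             # last SNP <= r
      ok <- li <= length(snps) & ri >= 1L & li < ri
      l <- snps[pmin(li, length(snps))][ok]
      r <- snps[pmax(ri, 1L)][ok]
      d <- r - l
    }
    d_all <- c(d_all, d); l_all <- c(l_all, l)
  }
  cum_d <- cumsum(as.numeric(d_all))
  n <- which(cum_d >= target_bp)[1]
  if (is.na(n)) n <- length(d_all)
  d <- d_all[seq_len(n)]; l <- l_all[seq_len(n)]
  r <- l + d
  d_cM <- cumulative_cM(ref, r) - cumulative_cM(ref, l)
  p_c <- (1 - exp(-2 * d_cM / 100)) / 2   # Haldane, cM -> Morgans
  true_c <- runif(n) < p_c
  flip <- runif(n) < error_rate
  obs_c <- xor(true_c, flip)
  pairs <- data.frame(chrom = chrom, left_pos = l, right_pos = r,
                      status = ifelse(obs_c, "C", "N"),
                      b1 = base_err, p1 = phase_err,
                      b2 = base_err, p2 = phase_err,
                      d = d, stringsAsFactors = FALSE)
  attr(pairs, "truth") <- true_c
  attr(pairs, "realized_coverage") <- sum(as.numeric(d)) / L
  pairs
}

#' Compare reconstructed maps against the reference at multiple scales
#'
#' Bins the genome at each scale, totals the genetic length (cM) of every
#' map per bin over the span shared by the reference and the
#' reconstruction, and reports the Pearson correlation per replicate and
#' scale, the mean correlation per scale, and the relative bias of the mean
#' per-bp rate. Scales yielding fewer than 3 bins (or zero variance) give
#' `NA`.
#'
#' @param ref Reference `recomb_map`.
#' @param maps A `recomb_map` or list of them (replicates).
#' @param scales Bin widths in bp (default 2 kb, 10 kb, 100 kb, 1 Mb,
#'   5 Mb).
#' @return List with `correlations` (data.frame scale x replicate),
#'   `mean_correlation` (named by scale), and `rate_bias` (per replicate,
#'   `(mean_r_hat - mean_r_ref)/mean_r_ref` over the shared span).
#' @export
evaluate_reconstruction <- function(ref, maps,
                                    scales = c(2e3, 1e4, 1e5, 1e6, 5e6)) {
  if (inherits(maps, "recomb_map")) maps <- list(maps)
  cors <- matrix(NA_real_, nrow = length(scales), ncol = length(maps),
                 dimnames = list(paste0("scale_", scales), NULL))
  bias <- numeric(length(maps))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    span <- c(max(min(ref$start), min(m$start)), min(max(ref$end), max(m$end)))
    span_len <- span[2] - span[1]
    ref_tot <- cumulative_cM(ref, span[2]) - cumulative_cM(ref, span[1])
    map_tot <- cumulative_cM(m, span[2]) - cumulative_cM(m, span[1])
    bias[k] <- (map_tot - ref_tot) / ref_tot
    for (s in seq_along(scales)) {
      nb <- floor(span_len / scales[s])
      if (nb < 3) next
      edges <- span[1] + scales[s] * (0:nb)
      x <- diff(cumulative_cM(ref, edges))
      y <- diff(cumulative_cM(m, edges))
      # constant bin totals (up to rounding) leave the correlation undefined
      if (stats::sd(x) <= 1e-9 * max(mean(x), 1e-300) ||
          stats::sd(y) <= 1e-9 * max(mean(y), 1e-300)) next
      cors[s, k] <- stats::cor(x, y)
    }
  }
  list(correlations = as.data.frame(cors),
       mean_correlation = rowMeans(cors, na.rm = FALSE),
       rate_bias = bias)
}
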