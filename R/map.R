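#' @importFrom stats approx quantile runif rbinom setNames weighted.mean
#' @importFrom utils head tail
NULL

new_recomb_map <- function(df, chrom, span) {
  structure(df, chrom = chrom, retained_span = span,
            class = c("recomb_map", "data.frame"))
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("<recomb_map> %s: %d intervals on [%g, %g), %.3f cM\n",
              attr(x, "chrom"), nrow(x), attr(x, "retained_span")[1],
              attr(x, "retained_span")[2], map_length_cM(x)))
  invisible(x)
}

#' Total genetic length of a map
#'
#' Sums `rate * length` over all intervals. Rates are stored in cM/bp, so
#' the result is in centimorgans; divide by 100 for Morgans.
#'
#' @param map A `recomb_map` (or any data.frame with `start`, `end`,
#'   `rate`).
#' @return Total genetic length in cM.
#' @export
map_length_cM <- function(map) {
  sum(map$rate * (map$end - map$start))
}

# Interval grid shared by initial_map and em_refine. Boundaries are the
# union of all pair-bounding SNP coordinates clipped to the retained span;
# each C pair is assigned the index range of grid intervals inside its
# clipped span. N is the effective coverage on each grid interval.
build_map_grid <- function(pairs, profile, span) {
  keep <- pairs$right_pos > span[1] & pairs$left_pos < span[2]
  pr <- pairs[keep, , drop = FALSE]
  b <- sort(unique(pmin(pmax(c(pr$left_pos, pr$right_pos), span[1]), span[2])))
  b <- sort(unique(c(b, span)))
  m <- length(b) - 1L
  len <- diff(b)
  N <- coverage_at(profile, b[-length(b)])
  cpair <- pr[pr$status == "C" & pr$P > 0, , drop = FALSE]
  l <- pmax(cpair$left_pos, span[1])
  r <- pmin(cpair$right_pos, span[2])
  si <- findInterval(l, b)
  ei <- findInterval(r, b) - 1L
  list(b = b, len = len, N = N, m = m,
       rho = cpair$P / cpair$d,   # per-bp crossover density of each C pair
       si = si, ei = ei, chrom = pr$chrom[1])
}

diff_cumsum <- function(add, si, ei, m) {
  # sum of `add` over all index ranges [si, ei] covering each interval
  arr <- numeric(m + 1L)
  for (k in seq_along(add)) {
    arr[si[k]] <- arr[si[k]] + add[k]
    arr[ei[k] + 1L] <- arr[ei[k] + 1L] - add[k]
  }
  cumsum(arr)[seq_len(m)]
}

#' Initial recombination map from posterior-weighted pairs
#'
#' Distributes each crossover pair's posterior probability uniformly over
#' the basepairs between its two outermost SNPs (per-bp density
#' `P_i / d_i`), sums the densities at each basepair, and normalises by the
#' effective coverage there: intervals surveyed by many pairs need
#' proportionally more crossover mass for the same rate. On the grid
#' delimited by all bounding-SNP coordinates within the retained span,
#' \deqn{\mathrm{rate}_j = 100 \sum_{i \ni j} (P_i/d_i) / N_j \quad \mathrm{cM/bp}.}
#'
#' @param pairs Informative pairs with posterior column `P` (see
#'   [posterior_crossover()]).
#' @param profile A `coverage_profile` for the same pairs.
#' @param retained_span Half-open `c(start, end)` from [edge_trim()].
#' @return A `recomb_map` with columns `chrom`, `start`, `end` (half-open
#'   intervals) and `rate` (cM/bp).
#' @export
initial_map <- function(pairs, profile = NULL, retained_span = NULL) {
  if (is.null(profile)) profile <- effective_coverage(pairs)
  if (is.null(retained_span)) retained_span <- edge_trim(profile, min_cov = 0)
  if (anyNA(retained_span))
    return(new_recomb_map(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), rate = numeric()),
                          pairs$chrom[1], retained_span))
  g <- build_map_grid(pairs, profile, retained_span)
  D <- diff_cumsum(g$rho, g$si, g$ei, g$m)
  rate <- numeric(g$m)
  pos <- g$N > 0
  if (any(D > 0 & !pos))
    warning("zero effective coverage inside retained span; rate set to 0 there")
  rate[pos] <- 100 * D[pos] / g$N[pos]
  new_recomb_map(data.frame(chrom = g$chrom, start = g$b[-length(g$b)],
                            end = g$b[-1], rate = rate),
                 g$chrom, retained_span)
}

#' Refine a recombination map by expectation-maximisation
#'
#' The initial map spreads each pair's crossover mass uniformly along its
#' insert; the EM procedure instead lets the pairs localise each other's
#' crossovers. Each crossover pair carries a fixed genetic mass
#' \eqn{G_i = (P_i/d_i) \sum_{j \in \mathrm{span}_i} \mathrm{len}_j / N_j}
#' (its posterior, normalised once by the effective coverage under the
#' initial uniform spread). The E-step redistributes \eqn{G_i} over the
#' intervals inside the pair's span proportionally to the current
#' \eqn{\mathrm{rate}_j \cdot \mathrm{len}_j} (uniformly when the span's
#' total rate is 0); the M-step sets
#' \eqn{\mathrm{rate}_j = \sum_i w_{ij} / \mathrm{len}_j}. Because each
#' pair's redistributed weights always sum to \eqn{G_i}, the total genetic
#' length of the map is conserved exactly at every iteration; under
#' constant effective coverage the update coincides with re-normalising the
#' redistributed posterior mass by \eqn{N_j \mathrm{len}_j}. Iteration
#' stops when the maximum relative per-interval rate change falls below
#' `tol` or after `max_iter` iterations (with a warning).
#'
#' @param map0 Initial map from [initial_map()].
#' @param pairs The posterior-weighted pairs used to build `map0`.
#' @param profile Coverage profile for the same pairs (recomputed when
#'   `NULL`).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative per-interval convergence tolerance (default 1e-4).
#' @return A refined `recomb_map` with attributes `iterations` and
#'   `converged`.
#' @export
em_refine <- function(map0, pairs, profile = NULL, max_iter = 100, tol = 1e-4) {
  if (!nrow(map0)) return(map0)
  if (is.null(profile)) profile <- effective_coverage(pairs)
  span <- attr(map0, "retained_span")
  g <- build_map_grid(pairs, profile, span)
  stopifnot(nrow(map0) == g$m)
  gl <- map0$rate * g$len / 100          # genetic mass per interval, Morgans
  if (!length(g$rho)) {
    attr(map0, "iterations") <- 0L
    attr(map0, "converged") <- TRUE
    return(map0)
  }
  # fixed per-pair genetic mass: coverage normalisation of the uniform spread
  inv_n <- ifelse(g$N > 0, g$len / g$N, 0)
  cum_invn <- c(0, cumsum(inv_n))
  G <- g$rho * (cum_invn[g$ei + 1L] - cum_invn[g$si])
  iter <- 0L
  converged <- FALSE
  floor_r <- max(gl) * 1e-9
  while (iter < max_iter) {
    iter <- iter + 1L
    cum_g <- c(0, cumsum(gl))
    S <- cum_g[g$ei + 1L] - cum_g[g$si]
    posS <- S > 0
    A <- diff_cumsum(ifelse(posS, G / ifelse(S > 0, S, 1), 0), g$si, g$ei, g$m)
    new_gl <- gl * A
    if (any(!posS)) {   # uniform fallback over the pair's span length
      cumlen <- c(0, cumsum(g$len))
      dens <- G[!posS] / (cumlen[g$ei[!posS] + 1L] - cumlen[g$si[!posS]])
      new_gl <- new_gl + g$len * diff_cumsum(dens, g$si[!posS], g$ei[!posS], g$m)
    }
    rel <- max(abs(new_gl - gl) / pmax(gl, floor_r))
    gl <- new_gl
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations (last relative change ", signif(rel, 3), ")")
  map0$rate <- 100 * gl / g$len
  attr(map0, "iterations") <- iter
  attr(map0, "converged") <- converged
  map0
}

#' Cumulative genetic position along a map
#'
#' Piecewise-linear cumulative cM from the start of the retained span;
#' constant extrapolation outside the map.
#'
#' @param map A `recomb_map` (or reference map in the same layout).
#' @param x Physical positions (bp).
#' @return Cumulative cM at `x`.
#' @export
cumulative_cM <- function(map, x) {
  if (!nrow(map)) return(rep(0, length(x)))
  b <- c(map$start[1], map$end)
  cum <- c(0, cumsum(map$rate * (map$end - map$start)))
  approx(b, cum, xout = x, rule = 2)$y
}

#' Infer a recombination map from informative pairs
#'
#' Runs the full single-chromosome inference chain: pair likelihoods,
#' imbalanced-SNP filtering, baseline-rate and correction-factor
#' estimation, double-crossover adjustment, posterior crossover
#' probabilities, effective-coverage edge trimming, initial map and EM
#' refinement.
#'
#' @param pairs Informative pairs (`data.frame` from
#'   [find_informative_pairs()] or [read_pairs()]). Multiple chromosomes are
#'   processed independently.
#' @param long_threshold,short_threshold Insert thresholds (bp) for the
#'   baseline rate and correction factor (defaults 1e6 / 1e3).
#' @param c_min,n_max Imbalanced-SNP thresholds (defaults 2 / 0).
#' @param min_d_double Minimum insert for the double-crossover adjustment
#'   (default 1e6 bp).
#' @param min_cov Edge-trim coverage cutoff; default 10% of the
#'   length-weighted median effective coverage.
#' @param max_iter,tol EM controls.
#' @return For one chromosome, a `recomb_fit`: list with `map`
#'   (`recomb_map`), `model` (`rate_model`), `profile`, `retained_span` and
#'   `counts`. For several chromosomes, a named list of `recomb_fit`s.
#' @export
recomb_map <- function(pairs, long_threshold = 1e6, short_threshold = 1000,
                       c_min = 2, n_max = 0, min_d_double = 1e6,
                       min_cov = NULL, max_iter = 100, tol = 1e-4) {
  chroms <- unique(pairs$chrom)
  if (length(chroms) > 1L) {
    fits <- lapply(chroms, function(ch)
      recomb_map(pairs[pairs$chrom == ch, , drop = FALSE], long_threshold,
                 short_threshold, c_min, n_max, min_d_double, min_cov,
                 max_iter, tol))
    return(setNames(fits, chroms))
  }
  pairs <- pair_likelihoods(pairs)
  fil <- filter_imbalanced_snps(pairs, c_min, n_max)
  pairs <- fil$pairs
  model <- rate_model(pairs, long_threshold, short_threshold)
  pairs <- double_crossover_adjust(pairs, model, min_d_double)
  pairs <- posterior_crossover(pairs, model)
  profile <- effective_coverage(pairs)
  span <- edge_trim(profile, min_cov)
  map0 <- initial_map(pairs, profile, span)
  map <- em_refine(map0, pairs, profile, max_iter, tol)
  structure(list(map = map, model = model, profile = profile,
                 retained_span = span, pairs = pairs,
                 counts = list(n_pairs = nrow(pairs),
                               n_removed_snps = nrow(fil$removed_snps))),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  print(x$model)
  print(x$map)
  invisible(x)
}

#' Write / read the tab-delimited recombination map format
#'
#' Columns: `chrom`, `start`, `end` (1-based inclusive), `rate_cM_per_Mb`,
#' `cumulative_cM`; bootstrap maps add `lo95_cM_per_Mb` / `hi95_cM_per_Mb`.
#'
#' @param map A `recomb_map` or `map_ci`.
#' @param path File path.
#' @return `write_recomb_map` returns `path` invisibly; `read_recomb_map`
#'   returns a `recomb_map` (or `map_ci` when envelope columns are
#'   present).
#' @export
write_recomb_map <- function(map, path) {
  rate <- if (!is.null(map$rate)) map$rate else map$mean
  out <- data.frame(chrom = map$chrom, start = map$start, end = map$end - 1,
                    rate_cM_per_Mb = rate * 1e6,
                    cumulative_cM = cumsum(rate * (map$end - map$start)))
  if (!is.null(map$lo95)) {
    out$lo95_cM_per_Mb <- map$lo95 * 1e6
    out$hi95_cM_per_Mb <- map$hi95 * 1e6
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end + 1,
                    rate = df$rate_cM_per_Mb / 1e6)
  if (!is.null(df$lo95_cM_per_Mb)) {
    out$mean <- out$rate
    out$lo95 <- df$lo95_cM_per_Mb / 1e6
    out$hi95 <- df$hi95_cM_per_Mb / 1e6
    return(structure(out, chrom = df$chrom[1],
                     retained_span = c(out$start[1], out$end[nrow(out)]),
                     class = c("map_ci", "data.frame")))
  }
  new_recomb_map(out, df$chrom[1], c(out$start[1], out$end[nrow(out)]))
}
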