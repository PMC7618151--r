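step_rate_at <- function(map, x, col = "rate") {
  # piecewise-constant rate lookup on half-open intervals; NA outside
  if (!nrow(map)) return(rep(NA_real_, length(x)))
  idx <- findInterval(x, c(map$start, map$end[nrow(map)]))
  out <- rep(NA_real_, length(x))
  ok <- idx >= 1L & idx <= nrow(map) & x < map$end[pmax(idx, 1L)]
  out[ok] <- map[[col]][idx[ok]]
  out
}

#' Bootstrap recombination maps with confidence envelope
#'
#' Resamples the informative read pairs with replacement `B` times and
#' reruns the whole inference chain from the baseline-rate estimate onward
#' for each resample (the imbalanced-SNP filter is applied once,
#' beforehand, on the observed pairs). Replicate maps are evaluated on the
#' union of their interval grids, restricted to the intersection of their
#' retained spans, and summarised per interval by the mean and the 2.5/97.5
#' percentile envelope.
#'
#' @param pairs Informative pairs (one chromosome).
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed for reproducible resampling.
#' @inheritParams recomb_map
#' @return A `map_ci`: `data.frame` with `chrom`, `start`, `end`, `mean`,
#'   `lo95`, `hi95` (rates in cM/bp) and attributes `n_boot`, `chrom`,
#'   `retained_span`.
#' @export
bootstrap_maps <- function(pairs, B = 50, seed = NULL, long_threshold = 1e6,
                           short_threshold = 1000, c_min = 2, n_max = 0,
                           min_d_double = 1e6, min_cov = NULL,
                           max_iter = 100, tol = 1e-4) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  pairs <- pair_likelihoods(pairs)
  pairs <- filter_imbalanced_snps(pairs, c_min, n_max)$pairs
  one <- function(p) {
    model <- rate_model(p, long_threshold, short_threshold)
    p <- double_crossover_adjust(p, model, min_d_double)
    p <- posterior_crossover(p, model)
    prof <- effective_coverage(p)
    span <- edge_trim(prof, min_cov)
    em_refine(initial_map(p, prof, span), p, prof, max_iter, tol)
  }
  maps <- vector("list", B)
  for (k in seq_len(B)) {
    idx <- sample.int(nrow(pairs), replace = TRUE)
    maps[[k]] <- one(pairs[idx, , drop = FALSE])
  }
  spans <- vapply(maps, function(m) attr(m, "retained_span"), numeric(2))
  span <- c(max(spans[1, ]), min(spans[2, ]))
  if (span[1] >= span[2]) stop("bootstrap retained spans do not overlap")
  b <- sort(unique(unlist(lapply(maps, function(m) c(m$start, m$end)))))
  b <- c(span[1], b[b > span[1] & b < span[2]], span[2])
  starts <- b[-length(b)]
  rates <- vapply(maps, function(m) step_rate_at(m, starts), numeric(length(starts)))
  rates <- matrix(rates, nrow = length(starts))
  q <- t(apply(rates, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
               names = FALSE))
  out <- data.frame(chrom = maps[[1]]$chrom[1], start = starts, end = b[-1],
                    mean = rowMeans(rates, na.rm = TRUE),
                    lo95 = q[, 1], hi95 = q[, 2])
  structure(out, chrom = maps[[1]]$chrom[1], retained_span = span, n_boot = B,
            class = c("map_ci", "data.frame"))
}

#' @export
print.map_ci <- function(x, ...) {
  cat(sprintf("<map_ci> %s: %d intervals on [%g, %g), mean length %.3f cM (%d bootstraps)\n",
              attr(x, "chrom"), nrow(x), attr(x, "retained_span")[1],
              attr(x, "retained_span")[2],
              sum(x$mean * (x$end - x$start)), attr(x, "n_boot")))
  invisible(x)
}

length_weighted_mean_rate <- function(m) {
  sum(m$mean * (m$end - m$start)) / sum(m$end - m$start)
}

#' Significant rate-difference regions between two bootstrap maps
#'
#' Identifies the maximal genomic intervals where the 95% bootstrap
#' envelopes of two maps do not intersect (closed-interval convention:
#' touching envelopes intersect). With `normalize = TRUE`, each map and its
#' envelope are first divided by that map's length-weighted mean rate over
#' its retained intervals, so only landscape-shape differences remain.
#'
#' @param a,b `map_ci` objects on the same chromosome.
#' @param normalize Divide each map by its mean rate before comparing.
#' @return List with `regions` (`data.frame` of `chrom`, `start`, `end`),
#'   `total_bp`, `fraction` of the compared span, and `compared_span`.
#' @export
delta_r_regions <- function(a, b, normalize = FALSE) {
  span <- c(max(attr(a, "retained_span")[1], attr(b, "retained_span")[1]),
            min(attr(a, "retained_span")[2], attr(b, "retained_span")[2]))
  chrom <- attr(a, "chrom")
  empty <- list(regions = data.frame(chrom = character(), start = numeric(),
                                     end = numeric()),
                total_bp = 0, fraction = 0, compared_span = span)
  if (span[1] >= span[2]) {
    warning("retained spans of the two maps do not overlap")
    return(empty)
  }
  if (normalize) {
    mu_a <- length_weighted_mean_rate(a)
    mu_b <- length_weighted_mean_rate(b)
    for (nm in c("mean", "lo95", "hi95")) {
      a[[nm]] <- a[[nm]] / mu_a
      b[[nm]] <- b[[nm]] / mu_b
    }
  }
  bd <- sort(unique(c(a$start, a$end, b$start, b$end)))
  bd <- c(span[1], bd[bd > span[1] & bd < span[2]], span[2])
  starts <- bd[-length(bd)]
  lo_a <- step_rate_at(a, starts, "lo95"); hi_a <- step_rate_at(a, starts, "hi95")
  lo_b <- step_rate_at(b, starts, "lo95"); hi_b <- step_rate_at(b, starts, "hi95")
  disjoint <- !is.na(lo_a) & !is.na(lo_b) & (hi_a < lo_b | hi_b < lo_a)
  if (!any(disjoint)) return(empty)
  r <- rle(disjoint)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  sel <- r$values
  regions <- data.frame(chrom = chrom, start = starts[starts_idx[sel]],
                        end = bd[-1][ends_idx[sel]])
  total <- sum(regions$end - regions$start)
  list(regions = regions, total_bp = total,
       fraction = total / (span[2] - span[1]), compared_span = span)
}
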