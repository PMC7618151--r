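#' Effective coverage profile
#'
#' The effective coverage at a genomic position is the number of informative
#' read pairs whose span contains it. Pair spans are treated half-open,
#' `[left_pos, right_pos)`, so that the surveyed basepairs of a pair sum
#' exactly to its insert size `d`. The profile is piecewise constant between
#' the pair endpoints and is computed by +1/-1 difference events.
#'
#' @param pairs Informative pairs (one chromosome).
#' @param boundaries Optional extra coordinates to include as interval
#'   breaks.
#' @return A `coverage_profile`: `data.frame` with `start`, `end`
#'   (half-open) and `count`, plus a `chrom` attribute.
#' @export
effective_coverage <- function(pairs, boundaries = NULL) {
  b <- sort(unique(c(pairs$left_pos, pairs$right_pos, boundaries)))
  if (length(b) < 2L) {
    prof <- data.frame(start = integer(), end = integer(), count = numeric())
  } else {
    cnt <- interval_cover_counts(pairs$left_pos, pairs$right_pos, b)
    prof <- data.frame(start = b[-length(b)], end = b[-1], count = cnt)
  }
  structure(prof, chrom = pairs$chrom[1], class = c("coverage_profile", "data.frame"))
}

# Number of spans [l, r) fully covering each grid interval [b_t, b_{t+1}).
# Since every l and r is a grid point, a span covers intervals idx(l) ..
# idx(r) - 1; counted with a difference array.
interval_cover_counts <- function(l, r, b) {
  m <- length(b) - 1L
  diffarr <- numeric(m + 1L)
  si <- findInterval(l, b)
  ei <- findInterval(r, b) - 1L
  ok <- ei >= si
  for (k in which(ok)) {
    diffarr[si[k]] <- diffarr[si[k]] + 1
    diffarr[ei[k] + 1L] <- diffarr[ei[k] + 1L] - 1
  }
  cumsum(diffarr)[seq_len(m)]
}

#' Coverage at single positions
#'
#' @param profile A `coverage_profile`.
#' @param x Positions.
#' @return Effective coverage at each position (0 outside all pair spans).
#' @export
coverage_at <- function(profile, x) {
  if (!nrow(profile)) return(rep(0, length(x)))
  idx <- findInterval(x, c(profile$start, profile$end[nrow(profile)]))
  inside <- idx >= 1L & idx <= nrow(profile) & x < profile$end[pmax(idx, 1L)]
  out <- rep(0, length(x))
  out[inside] <- profile$count[idx[inside]]
  out
}

#' Trim chromosome edges by minimum effective coverage
#'
#' Effective coverage decays toward chromosome ends, inflating sampling
#' noise that the EM procedure can propagate far inland. Scanning inward
#' from each end, the retained span starts at the first interval whose
#' coverage reaches `min_cov` and ends at the last such interval. Interior
#' dips below `min_cov` are deliberately not trimmed.
#'
#' @param profile A `coverage_profile`.
#' @param min_cov Minimum effective coverage. Default: 10% of the
#'   length-weighted median coverage of the profile.
#' @return Numeric `c(start, end)`, half-open, or `c(NA, NA)` with a
#'   warning when coverage never reaches `min_cov`.
#' @export
edge_trim <- function(profile, min_cov = NULL) {
  if (!nrow(profile)) {
    warning("empty coverage profile; nothing retained")
    return(c(NA_real_, NA_real_))
  }
  if (is.null(min_cov)) {
    med <- weighted_median(profile$count, profile$end - profile$start)
    min_cov <- 0.1 * med
  }
  ok <- profile$count >= min_cov
  if (!any(ok)) {
    warning("effective coverage never reaches min_cov = ", min_cov,
            "; map would be empty")
    return(c(NA_real_, NA_real_))
  }
  c(profile$start[which(ok)[1]], profile$end[rev(which(ok))[1]])
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
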