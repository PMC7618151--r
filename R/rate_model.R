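#' Estimate the chromosome baseline crossover rate from long-insert pairs
#'
#' Long-insert read pairs (default insert > 1 Mb) have a highly favourable
#' ratio of true to false crossover calls, because the probability that a
#' genuine crossover falls between the two reads grows linearly with the
#' insert length while false positives do not. The baseline per-bp
#' crossover rate is estimated as the crossover likelihood mass among long
#' crossover pairs divided by the total basepairs surveyed by all long
#' pairs:
#' \deqn{r^* = \sum_{i \in \mathrm{long}, C} l_{c,i} \Big/ \sum_{i \in \mathrm{long}} d_i}
#' in Morgans per bp (expected crossovers per bp per gamete).
#'
#' @param pairs Informative pairs with `lc` (see [pair_likelihoods()]) and
#'   `d`.
#' @param long_threshold Inserts strictly greater than this are "long"
#'   (default 1e6 bp).
#' @return Baseline rate `r_star` (Morgans/bp).
#' @export
estimate_baseline_rate <- function(pairs, long_threshold = 1e6) {
  long <- pairs$d > long_threshold
  if (!any(long))
    stop("no read pairs with insert > ", long_threshold,
         " bp; lower `long_threshold` to estimate the baseline rate")
  sum(pairs$lc[long & pairs$status == "C"]) / sum(as.numeric(pairs$d[long]))
}

#' Estimate the false-positive correction factor from short-insert pairs
#'
#' Short-insert pairs (default < 1 kb) almost never contain a genuine
#' crossover, so their aggregate crossover likelihood in excess of the
#' baseline expectation measures the per-pair false-positive crossover
#' rate:
#' \deqn{f = \left(\sum_i l_{c,i} - \sum_i d_i r^*\right) / n_s}
#' where the sums and the count \eqn{n_s} run over all short-insert
#' informative pairs (pairs observed as `N` contribute `lc = 0` under the
#' conservative convention, so only observed-`C` pairs add likelihood mass
#' while every short pair contributes its expected true-positive mass
#' \eqn{d_i r^*} and to the denominator). `f` is clamped into `[0, 1)`.
#'
#' @param pairs Informative pairs with `lc` and `d`.
#' @param r_star Baseline rate from [estimate_baseline_rate()].
#' @param short_threshold Inserts strictly below this are "short"
#'   (default 1000 bp).
#' @return Correction factor `f` (dimensionless); 0 when no short pairs
#'   exist.
#' @export
correction_factor <- function(pairs, r_star, short_threshold = 1000) {
  short <- pairs$d < short_threshold
  ns <- sum(short)
  if (ns == 0L) return(0)
  f <- (sum(pairs$lc[short]) - sum(as.numeric(pairs$d[short])) * r_star) / ns
  min(max(f, 0), 1 - 1e-12)
}

#' Per-chromosome rate model
#'
#' Bundles the baseline per-bp crossover rate and the false-positive
#' correction factor with the insert-length thresholds they were estimated
#' under.
#'
#' @param pairs Informative pairs (single chromosome) with likelihood
#'   columns.
#' @param long_threshold,short_threshold Insert-length thresholds in bp
#'   (defaults: long > 1 Mb, short < 1 kb).
#' @return An object of class `rate_model`: list with `chrom`, `r_star`
#'   (Morgans/bp), `f`, `long_threshold`, `short_threshold`.
#' @export
rate_model <- function(pairs, long_threshold = 1e6, short_threshold = 1000) {
  stopifnot(long_threshold > short_threshold)
  r_star <- estimate_baseline_rate(pairs, long_threshold)
  f <- correction_factor(pairs, r_star, short_threshold)
  structure(list(chrom = pairs$chrom[1], r_star = r_star, f = f,
                 long_threshold = long_threshold,
                 short_threshold = short_threshold),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s: r* = %.4g M/bp, f = %.4g (long > %g bp, short < %g bp)\n",
              x$chrom, x$r_star, x$f, x$long_threshold, x$short_threshold))
  invisible(x)
}

#' Adjust likelihoods of long non-crossover pairs for double crossovers
#'
#' A read pair spanning two crossovers is observed as `N` although
#' recombination occurred twice between its reads. With the expected
#' crossover count on the insert \eqn{\lambda = r^* d}, the probability of
#' exactly two crossovers is the Poisson mass
#' \eqn{p_d = \lambda^2 e^{-\lambda} / 2}. For long-insert pairs observed as
#' `N` the conservative convention is relaxed to `lc = pd`, `ln = 1 - pd`.
#' Because crossover interference suppresses nearby double crossovers, the
#' adjustment is restricted to inserts above `min_d` (default 1 Mb).
#'
#' @param pairs Informative pairs with `lc`, `ln`, `d`.
#' @param model A `rate_model`.
#' @param min_d Only status-`N` pairs with `d > min_d` are adjusted.
#' @return `pairs` with adjusted `lc`/`ln`.
#' @export
double_crossover_adjust <- function(pairs, model, min_d = 1e6) {
  sel <- pairs$status == "N" & pairs$d > min_d
  if (any(sel)) {
    lam <- model$r_star * pairs$d[sel]
    pd <- lam^2 * exp(-lam) / 2
    pairs$lc[sel] <- pd
    pairs$ln[sel] <- 1 - pd
  }
  pairs
}

#' Posterior crossover probability of informative pairs
#'
#' Combines the corrected likelihoods with an insert-length-dependent prior
#' under a uniform-rate assumption. The prior for pair `i` is
#' \eqn{p_{c,i} = r^* d_i} (clamped to `[0, 1]`) and the posterior for a
#' pair observed as crossover is
#' \deqn{P(c_i) = \frac{(l_c - f)\, p_c}{(l_c - f)\, p_c + (l_n + f)(1 - p_c)}}
#' with \eqn{l_c - f} floored at 0. Pairs observed as `N` obtain posterior 0
#' through the `lc = 0` convention (or the tiny double-crossover mass after
#' [double_crossover_adjust()], which is itself absorbed by the `-f`
#' correction unless the data are nearly error-free).
#'
#' @param pairs Informative pairs with `lc`, `ln`, `d`.
#' @param model A `rate_model`.
#' @return `pairs` with a posterior column `P` added.
#' @export
posterior_crossover <- function(pairs, model) {
  pc <- pmin(pmax(model$r_star * pairs$d, 0), 1)
  num <- pmax(pairs$lc - model$f, 0) * pc
  den <- num + (pairs$ln + model$f) * (1 - pc)
  degen <- den <= 0 & num <= 0
  if (any(den <= 0 & num > 0))
    warning("degenerate posterior denominator for ", sum(den <= 0 & num > 0),
            " pair(s); posterior set to 0")
  pairs$P <- ifelse(den > 0, num / den, 0)
  pairs$P[degen] <- 0
  pairs
}

#' Remove imbalanced SNPs and the read pairs they bound
#'
#' A phased SNP that bounds (i.e. is the outermost SNP of) at least `c_min`
#' crossover pairs while bounding at most `n_max` non-crossover pairs is
#' treated as a variant-calling or phasing artifact (defaults: >= 2 `C`,
#' 0 `N`). Such SNPs and all pairs they bound are removed; removal can
#' expose new imbalanced SNPs, so the rule is applied iteratively until
#' stable.
#'
#' @param pairs Informative pairs.
#' @param c_min Minimum number of bounded `C` pairs for imbalance
#'   (default 2).
#' @param n_max Maximum number of bounded `N` pairs tolerated (default 0).
#' @return List with `pairs` (kept rows) and `removed_snps` (data.frame of
#'   `chrom`, `pos`).
#' @export
filter_imbalanced_snps <- function(pairs, c_min = 2, n_max = 0) {
  removed <- list()
  repeat {
    if (!nrow(pairs)) break
    snp <- data.frame(
      chrom = c(pairs$chrom, pairs$chrom),
      pos = c(pairs$left_pos, pairs$right_pos),
      is_c = rep(pairs$status == "C", 2L))
    key <- paste(snp$chrom, snp$pos)
    nc <- tapply(snp$is_c, key, sum)
    nn <- tapply(!snp$is_c, key, sum)
    bad <- names(nc)[nc >= c_min & nn <= n_max]
    if (!length(bad)) break
    removed[[length(removed) + 1L]] <- bad
    pk_l <- paste(pairs$chrom, pairs$left_pos)
    pk_r <- paste(pairs$chrom, pairs$right_pos)
    pairs <- pairs[!(pk_l %in% bad | pk_r %in% bad), , drop = FALSE]
  }
  bad_all <- unique(unlist(removed))
  removed_df <- if (length(bad_all)) {
    parts <- regmatches(bad_all, regexpr(" ", bad_all), invert = TRUE)
    data.frame(chrom = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), pos = integer())
  rownames(pairs) <- NULL
  list(pairs = pairs, removed_snps = removed_df)
}
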