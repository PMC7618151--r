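# Brute-force oracles and small generators shared across tests.

# per-bp effective coverage: pair [l, r) contains x
brute_coverage <- function(pairs, x) {
  vapply(x, function(xx) sum(pairs$left_pos <= xx & xx < pairs$right_pos), 0)
}

# per-bp initial-map rate (cM/bp): sum of P_i/d_i over spanning C pairs,
# divided by the per-bp effective coverage
brute_initial_rate <- function(pairs, x) {
  vapply(x, function(xx) {
    n <- sum(pairs$left_pos <= xx & xx < pairs$right_pos)
    if (n == 0) return(0)
    sel <- pairs$status == "C" & pairs$left_pos <= xx & xx < pairs$right_pos
    100 * sum(pairs$P[sel] / pairs$d[sel]) / n
  }, 0)
}

# independent EM implementation: explicit per-pair loops, no difference
# arrays; same model as em_refine (fixed per-pair mass, redistribution
# proportional to interval genetic mass)
loop_em <- function(b, N, pairs_lr, P, n_iter) {
  m <- length(b) - 1L
  len <- diff(b)
  si <- findInterval(pairs_lr[, 1], b)
  ei <- findInterval(pairs_lr[, 2], b) - 1L
  rho <- P / (pairs_lr[, 2] - pairs_lr[, 1])
  gl <- numeric(m)
  G <- numeric(length(P))
  for (i in seq_along(P)) {
    for (j in si[i]:ei[i]) {
      gl[j] <- gl[j] + rho[i] * len[j] / N[j]
      G[i] <- G[i] + rho[i] * len[j] / N[j]
    }
  }
  for (it in seq_len(n_iter)) {
    new_gl <- numeric(m)
    for (i in seq_along(P)) {
      jj <- si[i]:ei[i]
      S <- sum(gl[jj])
      w <- if (S > 0) G[i] * gl[jj] / S else G[i] * len[jj] / sum(len[jj])
      new_gl[jj] <- new_gl[jj] + w
    }
    gl <- new_gl
  }
  gl
}

random_pairs <- function(n, chrom_len = 10000, chrom = "chrT",
                         p_c = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  l <- sample.int(chrom_len - 100L, n)
  d <- pmin(sample.int(chrom_len / 2L, n) + 10L, chrom_len - l)
  data.frame(chrom = chrom, left_pos = l, right_pos = l + d,
             status = ifelse(runif(n) < p_c, "C", "N"),
             b1 = 1e-4, p1 = 1e-6, b2 = 1e-4, p2 = 1e-6, d = d,
             stringsAsFactors = FALSE)
}

make_pairs <- function(l, r, status, chrom = "chrT", b = 1e-6, p = 1e-6) {
  data.frame(chrom = chrom, left_pos = l, right_pos = r, status = status,
             b1 = b, p1 = p, b2 = b, p2 = p, d = r - l,
             stringsAsFactors = FALSE)
}

flat_reference_map <- function(chrom_len, rate_cM_per_Mb, chrom = "chrSim") {
  structure(data.frame(chrom = chrom, start = 1, end = chrom_len,
                       rate = rate_cM_per_Mb / 1e6),
            chrom = chrom, retained_span = c(1, chrom_len),
            class = c("recomb_map", "data.frame"))
}
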