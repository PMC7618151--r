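test_that("baseline rate is the long-pair crossover mass per surveyed bp", {
  # 10 long pairs of 2 Mb, two of them crossovers with lc = 1
  p <- make_pairs(rep(1, 10), rep(2e6 + 1, 10),
                  c("C", "C", rep("N", 8)), b = 0, p = 0)
  p <- pair_likelihoods(p)
  expect_equal(estimate_baseline_rate(p), 2 / 2e7)
  # no crossovers among long pairs
  p0 <- pair_likelihoods(make_pairs(rep(1, 5), rep(2e6 + 1, 5), "N"))
  expect_equal(estimate_baseline_rate(p0), 0)
  # doubling every insert halves the rate
  p2 <- p
  p2$right_pos <- p2$left_pos + 2 * p2$d
  p2$d <- 2 * p2$d
  expect_equal(estimate_baseline_rate(p2), estimate_baseline_rate(p) / 2)
  # nothing above the threshold
  short <- pair_likelihoods(make_pairs(1, 500, "C"))
  expect_error(estimate_baseline_rate(short), "long_threshold")
})

test_that("correction factor measures excess short-pair crossover likelihood", {
  # 5 short crossover pairs with lc = 1, d = 500, r* = 1e-8
  p <- pair_likelihoods(make_pairs(rep(1, 5), rep(501, 5), "C", b = 0, p = 0))
  expect_equal(correction_factor(p, 1e-8), (5 - 5 * 500 * 1e-8) / 5)
  expect_equal(correction_factor(p, 1e-8), 0.9999950)
  # no short pairs at all -> no evidence of false positives
  long <- pair_likelihoods(make_pairs(1, 2e6, "C"))
  expect_equal(correction_factor(long, 1e-8), 0)
  # clamped at zero when short pairs underperform the baseline
  pn <- pair_likelihoods(make_pairs(rep(1, 5), rep(501, 5), "N"))
  expect_equal(correction_factor(pn, 1e-3), 0)
})

fake_model <- function(r_star, f, chrom = "chrT") {
  structure(list(chrom = chrom, r_star = r_star, f = f,
                 long_threshold = 1e6, short_threshold = 1000),
            class = "rate_model")
}

test_that("posterior crossover probability matches direct arithmetic", {
  # worked example: lc=0.97, ln=0.03, f=0.01, r*=1e-8, d=1e6 -> pc=0.01
  p <- make_pairs(1, 1e6 + 1, "C")
  p$d <- 1e6
  p$lc <- 0.97; p$ln <- 0.03
  post <- posterior_crossover(p, fake_model(1e-8, 0.01))$P
  expect_equal(post, 0.0096 / (0.0096 + 0.0396), tolerance = 1e-12)
  expect_equal(post, 0.1951, tolerance = 1e-3)
  # certain crossover: f=0, lc=1, ln=0 -> P=1 for any positive prior
  p$lc <- 1; p$ln <- 0
  expect_equal(posterior_crossover(p, fake_model(1e-10, 0))$P, 1)
  # numerator vanishes when lc == f
  p$lc <- 0.01; p$ln <- 0.99
  expect_equal(posterior_crossover(p, fake_model(1e-8, 0.01))$P, 0)
  # observed-N pairs carry no posterior crossover mass
  pn <- pair_likelihoods(make_pairs(1, 5e5, "N"))
  expect_equal(posterior_crossover(pn, fake_model(1e-8, 0.01))$P, 0)
})

test_that("posterior increases with insert length and decreases with f", {
  base <- make_pairs(1, 1e5, "C")
  base$lc <- 0.97; base$ln <- 0.03
  post_at <- function(d, f) {
    p <- base; p$d <- d
    posterior_crossover(p, fake_model(1e-8, f))$P
  }
  d_grid <- c(1e4, 1e5, 1e6, 5e6)
  expect_true(all(diff(sapply(d_grid, post_at, f = 0.01)) > 0))
  f_grid <- c(0, 0.005, 0.05, 0.5)
  expect_true(all(diff(sapply(f_grid, function(f) post_at(1e6, f))) < 0))
})

test_that("imbalanced SNP filter applies the printed threshold cases", {
  # SNP 5000 bounds two C pairs and nothing else -> removed with its pairs
  p <- make_pairs(c(1000, 5000, 2000), c(5000, 9000, 8000), c("C", "C", "N"))
  res <- filter_imbalanced_snps(p)
  expect_equal(res$removed_snps$pos, 5000L)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$status, "N")
  # one bounded N pair protects the SNP
  p2 <- make_pairs(c(1000, 5000, 2000), c(5000, 9000, 5000), c("C", "C", "N"))
  res2 <- filter_imbalanced_snps(p2)
  expect_equal(nrow(res2$removed_snps), 0L)
  expect_equal(nrow(res2$pairs), 3L)
  # a single bounded C pair is not imbalanced
  p3 <- make_pairs(c(1000, 2000), c(5000, 8000), c("C", "N"))
  res3 <- filter_imbalanced_snps(p3)
  expect_equal(nrow(res3$removed_snps), 0L)
  expect_equal(nrow(res3$pairs), 2L)
})

test_that("imbalanced SNP removal cascades until stable under a relaxed N threshold", {
  # with n_max = 1: SNP 5000 (2 C, 1 N) goes first; removing its N pair
  # exposes SNP 7000 (2 C, then 1 N), which is only imbalanced afterwards
  p <- make_pairs(c(1000, 3000, 5000, 6000, 7000, 7000),
                  c(5000, 5000, 7000, 7000, 9000, 9500),
                  c("C", "C", "N", "N", "C", "C"))
  first <- filter_imbalanced_snps(p, c_min = 2, n_max = 1)
  expect_setequal(first$removed_snps$pos, c(5000L, 7000L))
  expect_equal(nrow(first$pairs), 0L)
  # with the default n_max = 0 the same input keeps everything: every SNP
  # bounds an N pair or fewer than two C pairs
  res0 <- filter_imbalanced_snps(p)
  expect_equal(nrow(res0$removed_snps), 0L)
})

test_that("double-crossover adjustment applies the Poisson mass to long N pairs only", {
  m <- fake_model(1e-7, 0)
  # lambda ~ 0.1 on an insert just above 1 Mb
  p2 <- double_crossover_adjust(pair_likelihoods(make_pairs(1, 1.0000001e6 + 1, "N")), m)
  lam <- 1e-7 * 1.0000001e6
  expect_equal(p2$lc, lam^2 * exp(-lam) / 2)
  expect_equal(p2$lc, 0.0045242, tolerance = 1e-4)
  expect_equal(p2$ln, 1 - p2$lc)
  # zero rate -> no change
  p0 <- double_crossover_adjust(pair_likelihoods(make_pairs(1, 2e6, "N")),
                                fake_model(0, 0))
  expect_equal(p0$lc, 0)
  expect_equal(p0$ln, 1)
  # short N pairs and C pairs untouched
  ps <- double_crossover_adjust(pair_likelihoods(make_pairs(1, 5e5, "N")), m)
  expect_equal(ps$lc, 0)
  pc <- pair_likelihoods(make_pairs(1, 2e6, "C", b = 0.01, p = 0))
  expect_equal(double_crossover_adjust(pc, m)$lc, pc$lc)
})

test_that("effective coverage equals brute-force per-bp counting", {
  # single pair
  p <- make_pairs(100, 900, "N")
  prof <- effective_coverage(p)
  expect_equal(coverage_at(prof, c(100, 500, 899)), c(1, 1, 1))
  expect_equal(coverage_at(prof, c(50, 900, 1000)), c(0, 0, 0))
  # nested pairs double the inner span
  p2 <- make_pairs(c(100, 300), c(900, 600), c("N", "N"))
  prof2 <- effective_coverage(p2)
  expect_equal(coverage_at(prof2, c(200, 400, 700)), c(1, 2, 1))
  # random pairs against the per-bp oracle on a 10 kb toy chromosome
  set.seed(21)
  pr <- random_pairs(20, chrom_len = 10000)
  prof3 <- effective_coverage(pr)
  x <- 1:10000
  expect_equal(coverage_at(prof3, x), brute_coverage(pr, x))
})

test_that("edge trimming scans inward and ignores interior dips", {
  # coverage ramp 0 -> high -> 0: symmetric tail trimming
  p <- make_pairs(c(0, 100, 200, 300), c(1000, 900, 800, 700), "N")
  prof <- effective_coverage(p)
  expect_equal(edge_trim(prof, min_cov = 3), c(200, 800))
  expect_equal(edge_trim(prof, min_cov = 1), c(0, 1000))
  # min_cov = 0 retains first to last endpoint
  expect_equal(edge_trim(prof, min_cov = 0), c(0, 1000))
  # interior dip is not trimmed
  pd <- make_pairs(c(0, 0, 600, 600, 0), c(400, 400, 1000, 1000, 1000), "N")
  profd <- effective_coverage(pd)
  expect_equal(coverage_at(profd, 500), 1)
  expect_equal(edge_trim(profd, min_cov = 2), c(0, 1000))
  # unreachable cutoff
  expect_warning(res <- edge_trim(prof, min_cov = 10), "never reaches")
  expect_true(all(is.na(res)))
})

test_that("initial map places the posterior mass of a single pair uniformly", {
  p <- make_pairs(1000, 2000, "C", b = 0, p = 0)
  p <- pair_likelihoods(p)
  p$P <- 1
  prof <- effective_coverage(p)
  m <- initial_map(p, prof, c(1000, 2000))
  # one crossover in one observed gamete across 1 kb: 0.1 cM per bp,
  # integrating to 1 Morgan
  expect_equal(unique(m$rate), 0.1)
  expect_equal(map_length_cM(m), 100)
  # two identical stacked pairs: numerator and coverage both double
  p2 <- rbind(p, p)
  m2 <- initial_map(p2, effective_coverage(p2), c(1000, 2000))
  expect_equal(unique(m2$rate), 0.1)
  # no crossover pairs -> all-zero map
  pn <- pair_likelihoods(make_pairs(1000, 2000, "N"))
  pn$P <- 0
  mn <- initial_map(pn, effective_coverage(pn), c(1000, 2000))
  expect_equal(unique(mn$rate), 0)
})

test_that("initial map equals the brute-force per-bp oracle on a toy chromosome", {
  set.seed(33)
  pr <- random_pairs(20, chrom_len = 10000, p_c = 0.6)
  pr <- pair_likelihoods(pr)
  pr$P <- ifelse(pr$status == "C", runif(nrow(pr)), 0)
  prof <- effective_coverage(pr)
  span <- c(min(pr$left_pos), max(pr$right_pos))
  m <- initial_map(pr, prof, span)
  x <- span[1]:(span[2] - 1)
  expect_equal(step_rate <- unname(vapply(x, function(xx) {
    i <- findInterval(xx, c(m$start, m$end[nrow(m)]))
    m$rate[i]
  }, 0)), brute_initial_rate(pr, x))
  # total genetic length agrees with per-bp summation
  expect_equal(map_length_cM(m), sum(brute_initial_rate(pr, x)))
})

test_that("EM leaves a single-pair map unchanged after one iteration", {
  p <- pair_likelihoods(make_pairs(1000, 3000, "C", b = 0, p = 0))
  p$P <- 0.8
  prof <- effective_coverage(p)
  m0 <- initial_map(p, prof, c(1000, 3000))
  m1 <- em_refine(m0, p, prof, max_iter = 50)
  expect_equal(m1$rate, m0$rate)
  expect_lte(attr(m1, "iterations"), 2L)
})

test_that("EM matches an independent loop implementation and concentrates overlap mass", {
  # two C pairs: one spans both intervals, one only the first
  p <- make_pairs(c(100, 100), c(300, 200), c("C", "C"), b = 0, p = 0)
  p <- pair_likelihoods(p)
  p$P <- 1
  prof <- effective_coverage(p)
  m0 <- initial_map(p, prof, c(100, 300))
  for (k in c(1, 3, 10)) {
    mk <- suppressWarnings(em_refine(m0, p, prof, max_iter = k, tol = 0))
    oracle <- loop_em(c(100, 200, 300), c(2, 1),
                      cbind(c(100, 100), c(300, 200)), c(1, 1), k)
    expect_equal(mk$rate * (mk$end - mk$start) / 100, oracle, tolerance = 1e-12)
  }
  # hand-solved fixed point: the shared interval absorbs all the mass
  # (G1 = 0.75, G2 = 0.5; the [200,300) mass y satisfies y' = y*G1/(x+y)
  # which only stabilises at y = 0, x = G1 + G2 = 1.25 Morgans)
  mf <- suppressWarnings(em_refine(m0, p, prof, max_iter = 3000, tol = 0))
  gl <- mf$rate * (mf$end - mf$start) / 100
  expect_equal(gl[1], 1.25, tolerance = 1e-3)
  expect_equal(gl[2], 0, tolerance = 1e-3)
  expect_equal(map_length_cM(mf), 125)
})

test_that("EM conserves total genetic length at every iteration on random fixtures", {
  set.seed(55)
  for (rep in 1:3) {
    pr <- random_pairs(40, chrom_len = 50000, p_c = 0.5)
    pr <- pair_likelihoods(pr)
    pr$P <- ifelse(pr$status == "C", runif(nrow(pr)), 0)
    prof <- effective_coverage(pr)
    span <- edge_trim(prof, min_cov = 1)
    m0 <- initial_map(pr, prof, span)
    len0 <- map_length_cM(m0)
    for (k in c(1, 2, 5, 20)) {
      mk <- suppressWarnings(em_refine(m0, pr, prof, max_iter = k, tol = 0))
      expect_equal(map_length_cM(mk), len0, tolerance = 1e-9)
    }
  }
})

test_that("total map length equals brute-force per-bp summation", {
  set.seed(8)
  b <- sort(sample.int(5000, 30))
  m <- structure(data.frame(chrom = "chrT", start = b[-30], end = b[-1],
                            rate = runif(29, 0, 1e-3)),
                 chrom = "chrT", retained_span = c(b[1], b[30]),
                 class = c("recomb_map", "data.frame"))
  x <- b[1]:(b[30] - 1)
  per_bp <- vapply(x, function(xx) m$rate[findInterval(xx, b)], 0)
  expect_equal(map_length_cM(m), sum(per_bp))
  expect_equal(map_length_cM(m),
               cumulative_cM(m, b[30]) - cumulative_cM(m, b[1]))
})
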