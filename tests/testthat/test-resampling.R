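test_that("BCa equals the percentile method when z0 = 0 and a = 0", {
  t0 <- 2
  # replicates exactly symmetric about t0 (half strictly below => z0 = 0),
  # jackknife symmetric about its mean (third central moment 0 => a = 0)
  d <- seq(0.01, 5, length.out = 500)
  reps <- c(t0 - d, t0 + d)
  jack <- 1:5
  ci <- bca_interval(reps, t0, jack, alpha = 0.05)
  expect_equal(attr(ci, "z0"), 0)
  expect_equal(attr(ci, "a"), 0)
  perc <- unname(stats::quantile(reps, c(0.025, 0.975), names = FALSE))
  expect_equal(as.numeric(ci), perc, tolerance = 1e-12)
})

test_that("degenerate replicate streams collapse to the point estimate", {
  ci <- bca_interval(rep(0.7, 500), 0.7, c(0.6, 0.7, 0.8))
  expect_equal(as.numeric(ci), c(0.7, 0.7))
  expect_true(attr(ci, "degenerate"))
  # zero jackknife variance => a = 0, interval still defined
  ci2 <- bca_interval(rnorm(500), 0, rep(0.5, 10))
  expect_equal(attr(ci2, "a"), 0)
  expect_error(bca_interval(rnorm(50), 0, 1:5), ">= 100")
  expect_error(bca_interval(rnorm(500), 0, c(1, 2)), "jackknife")
})

test_that("BCa intervals for a normal mean achieve nominal coverage", {
  set.seed(7)
  B <- 999; nrep <- 300; n <- 30
  cover <- 0
  for (r in seq_len(nrep)) {
    x <- rnorm(n)
    reps <- colMeans(matrix(x[sample.int(n, n * B, replace = TRUE)], n, B))
    jack <- (sum(x) - x) / (n - 1)
    ci <- bca_interval(reps, mean(x), jack, 0.05)
    cover <- cover + (ci[1L] <= 0 && 0 <= ci[2L])
  }
  mc_se <- sqrt(0.95 * 0.05 / nrep)
  expect_lte(abs(cover / nrep - 0.95), 2.5 * mc_se)
})

test_that("BCa endpoints agree with an independent reference implementation", {
  # boot::boot.ci computes BCa from its own replicate stream; endpoints
  # should agree with ours up to Monte-Carlo quantile noise at large B
  set.seed(51)
  x <- rnorm(40)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 10000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  set.seed(52)
  B <- 10000
  reps <- colMeans(matrix(x[sample.int(40, 40 * B, replace = TRUE)], 40, B))
  jack <- (sum(x) - x) / 39
  ours <- as.numeric(bca_interval(reps, mean(x), jack))
  expect_lt(max(abs(ours - ref)), 0.02)
})

test_that("bootstrap_kappa is deterministic under a fixed seed", {
  set.seed(21)
  p <- rand_rater_pair(40, 0.8)
  k1 <- bootstrap_kappa(p$a, p$b, seed = 99)
  k2 <- bootstrap_kappa(p$a, p$b, seed = 99)
  expect_identical(k1$ci, k2$ci)
  expect_identical(k1$estimate, k2$estimate)
  k3 <- bootstrap_kappa(p$a, p$b, seed = 100)
  expect_false(identical(k1$ci, k3$ci))
})

test_that("perfect agreement gives kappa 1 with a degenerate CI", {
  a <- setNames(rep(c("low", "unclear", "high"), each = 5), paste0("T", 1:15))
  k <- bootstrap_kappa(a, a, seed = 5)
  expect_equal(k$estimate, 1)
  expect_equal(k$ci, c(1, 1))
  expect_equal(k$band, "excellent")
})

test_that("zero-variance ratings yield a not-estimable bootstrap result", {
  a <- setNames(rep("high", 10), paste0("T", 1:10))
  k <- bootstrap_kappa(a, a, seed = 5)
  expect_false(k$estimable)
  expect_true(all(is.na(k$ci)))
  expect_equal(k$band, "NE")
})

test_that("kappa_difference of a comparison with itself is 0 with p = 1", {
  set.seed(22)
  p <- rand_rater_pair(40, 0.8)
  cmp <- list(p$a, p$b)
  d <- kappa_difference(cmp, cmp, seed = 33)
  expect_equal(d$delta, 0)
  expect_equal(d$p_two_sided, 1)
  expect_true(d$estimable)
})

test_that("kappa_difference flags NE when one comparison has no variance", {
  set.seed(23)
  p <- rand_rater_pair(30, 0.8)
  flat <- setNames(rep("low", 30), names(p$a))
  d <- kappa_difference(list(p$a, p$b), list(flat, flat), seed = 3)
  expect_false(d$estimable)
  expect_true(is.na(d$delta))
})

test_that("difference sign is recovered when one group is clearly better", {
  set.seed(24)
  hits <- 0
  for (r in 1:100) {
    pa <- rand_rater_pair(56, 0.95)
    pb <- rand_rater_pair(56, 0.60)
    names(pb$a) <- names(pb$b) <- names(pa$a)
    ka <- weighted_kappa(cross_tabulate(pa$a, pa$b))
    kb <- weighted_kappa(cross_tabulate(pb$a, pb$b))
    hits <- hits + (ka$estimable && kb$estimable &&
                      ka$estimate - kb$estimate > 0)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("p-values and BCa intervals are mutually consistent", {
  set.seed(25)
  for (r in 1:20) {
    pa <- rand_rater_pair(45, runif(1, 0.6, 0.95))
    pb <- rand_rater_pair(45, runif(1, 0.6, 0.95))
    names(pb$a) <- names(pb$b) <- names(pa$a)
    d <- kappa_difference(list(pa$a, pa$b), list(pb$a, pb$b),
                          n_replicates = 500, seed = r)
    if (!d$estimable || isTRUE(d$degenerate)) next
    excludes <- d$ci[1L] > 0 || d$ci[2L] < 0
    tol <- 1 / d$n_replicates
    if (excludes) expect_lte(d$p_two_sided, 0.05 + tol)
    else expect_gte(d$p_two_sided, 0.05 - tol)
  }
})

test_that("interaction_test returns NE for a level with fewer than 2 trials", {
  set.seed(26)
  p <- rand_rater_pair(20, 0.8)
  lvl_ok <- list(list(p$a, p$b), list(p$a, p$b))
  one <- lapply(list(p$a[1], p$b[1]), identity)
  lvl_tiny <- list(one, one)
  it <- interaction_test(list(big = lvl_ok, tiny = lvl_tiny), seed = 2)
  expect_false(it$estimable)
})

test_that("interaction statistic equals the difference of per-level deltas", {
  set.seed(27)
  mk_level <- function(prefix, acc_a, acc_b) {
    pa <- rand_rater_pair(40, acc_a, prefix = prefix)
    pb <- rand_rater_pair(40, acc_b, prefix = prefix)
    names(pb$a) <- names(pb$b) <- names(pa$a)
    list(list(pa$a, pa$b), list(pb$a, pb$b))
  }
  l1 <- mk_level("A", 0.95, 0.6)
  l2 <- mk_level("B", 0.6, 0.95)
  it <- interaction_test(list(x = l1, y = l2), seed = 9,
                         n_replicates = 200)
  expect_equal(unname(it$interaction),
               unname(it$delta_by_level[1L] - it$delta_by_level[2L]))
  expect_true(it$estimable)
  expect_gt(it$interaction, 0)  # opposite-sign deltas, sign recovered
})
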