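test_that("rater profiles must be row-stochastic", {
  expect_error(rater_profile(matrix(0.3, 3, 3)), "sum to 1")
  p <- accuracy_profile(0.9)
  expect_equal(unname(rowSums(unclass(p))), rep(1, 3))
  expect_equal(unname(diag(unclass(p))), rep(0.9, 3))
})

test_that("simulated truth follows the configured marginals", {
  cfg <- scenario_config(n_trials = 30, seed = 5)
  sim1 <- simulate_truth(cfg)
  sim2 <- simulate_truth(cfg)
  expect_identical(sim1$truth, sim2$truth)  # same seed, same draws
  expect_identical(sim1$meta, sim2$meta)

  # point-mass marginal: all trials get that rating
  cfg_pm <- scenario_config(n_trials = 20, marginals = c(1, 0, 0), seed = 2)
  pm <- simulate_truth(cfg_pm)
  expect_true(all(pm$truth$rating == "low"))

  # default template: empirical frequencies within 3 binomial SE, pooling
  # many seeds for one domain
  cfg56 <- scenario_config(n_trials = 56)
  n_rep <- 40
  counts <- c(low = 0, unclear = 0, high = 0)
  for (s in seq_len(n_rep)) {
    tr <- simulate_truth(cfg56, seed = 1000 + s)$truth
    r <- tr$rating[tr$domain == "allocation_concealment"]
    counts <- counts + table(r)
  }
  n <- 56 * n_rep
  p <- default_marginals()["allocation_concealment", ]
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(counts / n - p) <= pmax(3 * se, 1e-9)))
})

test_that("simulated raters follow their confusion rows", {
  cfg <- scenario_config(n_trials = 50, seed = 8)
  sim <- simulate_truth(cfg)
  # identity confusion reproduces the truth exactly; kappa vs truth is 1
  perfect <- simulate_rater(sim$truth, accuracy_profile(1), seed = 3)
  expect_equal(as.character(perfect$rating), as.character(sim$truth$rating))
  tv <- setNames(as.character(sim$truth$rating),
                 paste(sim$truth$trial_id, sim$truth$domain))
  rv <- setNames(as.character(perfect$rating),
                 paste(perfect$trial_id, perfect$domain))
  expect_equal(weighted_kappa(cross_tabulate(tv, rv))$estimate, 1)
  expect_error(simulate_rater(sim$truth, matrix(0.3, 3, 3)), "sum to 1")
})

test_that("a uniform rater is chance-level against the truth", {
  # expected kappa 0 analytically; empirical estimate within 3 SE at n = 10000
  uni <- rater_profile(matrix(1 / 3, 3, 3))
  m <- c(0.4, 0.35, 0.25)
  expect_equal(expected_kappa(m, accuracy_profile(1), uni), 0,
               tolerance = 1e-12)
  set.seed(31)
  n <- 10000
  truth <- data.frame(
    trial_id = paste0("T", 1:n), domain = "allocation_concealment",
    rating = sample(c("low", "unclear", "high"), n, TRUE, m)
  )
  r <- simulate_rater(truth, uni)
  tv <- setNames(as.character(truth$rating), truth$trial_id)
  rv <- setNames(as.character(r$rating), r$trial_id)
  k <- weighted_kappa(cross_tabulate(tv, rv))
  # SE of kappa at n = 10000 is below 0.013 here; 3 SE ~ 0.04
  expect_lt(abs(k$estimate), 0.04)
})

test_that("consensus follows the fidelity rule", {
  set.seed(32)
  n <- 10000
  truth <- data.frame(trial_id = paste0("T", 1:n), domain = "blinding_patients",
                      rating = rep("low", n))
  # rater A always matches truth, rater B never: every trial is a
  # disagreement in which exactly one answer equals the truth
  ra <- truth; ra$assessor_id <- "a"; ra$group <- "minimal"
  ra$stage <- "individual"
  rb <- ra; rb$assessor_id <- "b"; rb$rating <- "unclear"

  c1 <- simulate_consensus(ra, rb, truth, fidelity = 1, seed = 4)
  expect_true(all(c1$rating == "low"))

  c5 <- simulate_consensus(ra, rb, truth, fidelity = 0.5, seed = 4)
  frac_truth <- mean(c5$rating == "low")
  # closed form: 0.5 + 0.5 * 0.5 = 0.75; 3 binomial SE at n = 10000
  expect_lt(abs(frac_truth - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # agreement always passes through unchanged
  cA <- simulate_consensus(ra, ra, truth, fidelity = 0, seed = 4)
  expect_equal(as.character(cA$rating), as.character(ra$rating))

  expect_error(simulate_consensus(ra[1:10, ], rb, truth, 0.5), "coverage|same")
})

test_that("fidelity-1 consensus is never farther from truth than either rater", {
  set.seed(33)
  cfg <- scenario_config(n_trials = 80, seed = 12)
  sim <- simulate_truth(cfg)
  a <- simulate_rater(sim$truth, accuracy_profile(0.6), "a", "minimal")
  b <- simulate_rater(sim$truth, accuracy_profile(0.6), "b", "minimal")
  cons <- simulate_consensus(a, b, sim$truth, fidelity = 1)
  dist <- function(x) abs(as.integer(as_rating(x)) -
                            as.integer(as_rating(sim$truth$rating)))
  expect_true(all(dist(cons$rating) <=
                    pmin(dist(a$rating), dist(b$rating))))
})

test_that("expected_kappa matches large-sample simulation", {
  w <- weight_matrix()
  m <- c(0.3, 0.45, 0.25)
  A <- rater_profile(matrix(c(0.8, 0.15, 0.05,
                              0.1, 0.8, 0.1,
                              0.05, 0.25, 0.7), 3, 3, byrow = TRUE))
  B <- accuracy_profile(0.7)
  expect_equal(expected_kappa(m, accuracy_profile(1), accuracy_profile(1), w),
               1, tolerance = 1e-12)
  ek <- expected_kappa(m, A, B, w)
  set.seed(34)
  n <- 1e6
  truth <- sample(1:3, n, replace = TRUE, prob = m)
  draw <- function(P) {
    cum <- t(apply(unclass(P), 1, cumsum))
    u <- runif(n)
    1L + (u > cum[cbind(truth, 1L)]) + (u > cum[cbind(truth, 2L)])
  }
  lv <- c("low", "unclear", "high")
  tab <- table(factor(lv[draw(A)], lv), factor(lv[draw(B)], lv))
  emp <- weighted_kappa(matrix(tab, 3, 3), w)$estimate
  expect_lt(abs(emp - ek), 0.005)
  # degenerate: point-mass truth with perfect raters is NE
  expect_true(is.na(expected_kappa(c(1, 0, 0), accuracy_profile(1),
                                   accuracy_profile(1), w)))
})

test_that("tune_accuracy inverts expected_kappa", {
  w <- weight_matrix()
  m <- c(101, 102, 133) / 336
  for (target in c(0.4, 0.6, 0.95)) {
    acc <- tune_accuracy(target, m, w)
    expect_equal(expected_kappa(m, accuracy_profile(acc),
                                accuracy_profile(acc), w),
                 target, tolerance = 1e-6)
  }
})

test_that("build_scenario emits a complete study that re-validates", {
  cfg <- scenario_config(n_trials = 56, seed = 17)
  dir <- withr::local_tempdir()
  st <- build_scenario(cfg, dir = dir)
  # 6 raters individual + 3 pair consensus, 6 domains, 56 trials
  expect_equal(nrow(st$ratings), 56 * 6 * 9)
  expect_setequal(unique(st$ratings$stage), c("individual", "consensus"))
  expect_equal(length(unique(st$ratings$assessor_id)), 9L)
  # generated files re-validate through the readers without error
  back <- read_ratings(st$paths[["ratings"]])
  expect_equal(nrow(back), nrow(st$ratings))
  meta <- read_trial_meta(st$paths[["meta"]])
  expect_equal(nrow(meta), 56L)
  expect_error(scenario_config(n_trials = 0), "positive")
})
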