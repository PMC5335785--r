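# Independent oracles kept deliberately separate from package internals:
# naive double-loop summation for weighted kappa, the textbook closed form
# for unweighted Cohen's kappa, and small random-table / rating generators.

oracle_weighted_kappa <- function(tab, w) {
  n <- sum(tab)
  p_obs <- 0
  for (i in 1:3) for (j in 1:3) p_obs <- p_obs + w[i, j] * tab[i, j] / n
  r <- rowSums(tab); cc <- colSums(tab)
  p_exp <- 0
  for (i in 1:3) for (j in 1:3) p_exp <- p_exp + w[i, j] * r[i] * cc[j] / n^2
  if (1 - p_exp < 1e-12) return(NA_real_)
  (p_obs - p_exp) / (1 - p_exp)
}

oracle_cohen_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

random_table <- function(max_count = 20L) {
  matrix(sample(0:max_count, 9L, replace = TRUE), 3L, 3L)
}

# Named rating vectors for a rater pair with given accuracy, sharing truth.
rand_rater_pair <- function(n, accuracy, marginal = c(0.35, 0.35, 0.30),
                            prefix = "T") {
  lv <- c("low", "unclear", "high")
  truth <- sample(1:3, n, replace = TRUE, prob = marginal)
  cum <- t(apply(unclass(accuracy_profile(accuracy)), 1L, cumsum))
  draw <- function() {
    u <- stats::runif(n)
    1L + (u > cum[cbind(truth, 1L)]) + (u > cum[cbind(truth, 2L)])
  }
  ids <- paste0(prefix, seq_len(n))
  list(truth = stats::setNames(lv[truth], ids),
       a = stats::setNames(lv[draw()], ids),
       b = stats::setNames(lv[draw()], ids))
}

# Minimal valid ratings data.frame builder for I/O tests.
ratings_df <- function(trial_id, domain, assessor_id, group, stage,
                       rating) {
  data.frame(trial_id = trial_id, domain = domain,
             assessor_id = assessor_id, group = group, stage = stage,
             rating = rating, stringsAsFactors = FALSE)
}
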