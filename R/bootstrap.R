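# BCa bootstrap machinery for kappa, kappa differences, and stratum
# interactions. Resampling unit is always the trial; pairs of ratings are
# resampled intact, and joint contrasts share one resample per replicate so
# the correlation between statistics is preserved.

check_boot_settings <- function(n_replicates, alpha) {
  if (!is.numeric(n_replicates) || n_replicates < 100) {
    stop("n_replicates must be >= 100", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  invisible(NULL)
}

# Encode a joined pair of rating vectors as cell indices 1..9
# (cell = 3 * (a - 1) + b, row-major over the 3x3 table).
pair_cells <- function(a, b) {
  ai <- as.integer(as_rating(a))
  bi <- as.integer(as_rating(b))
  if (anyNA(ai) || anyNA(bi)) stop("missing ratings", call. = FALSE)
  3L * (ai - 1L) + bi
}

cells_to_table <- function(cells) {
  matrix(tabulate(cells, 9L), 3L, 3L, byrow = TRUE,
         dimnames = list(RATING_LEVELS, RATING_LEVELS))
}

# Vectorised kappa over the columns of a 9 x B cell-count matrix.
# Returns a length-B vector with NA where the statistic is not estimable.
kappa_cols <- function(cnt, w, tol = 1e-12) {
  wv <- as.vector(t(w))                  # row-major to match cell order
  n <- colSums(cnt)
  p_obs <- as.vector(wv %*% cnt) / n
  idx9 <- matrix(seq_len(9L), 3L, 3L, byrow = TRUE)
  r3 <- rbind(colSums(cnt[idx9[1L, ], , drop = FALSE]),
              colSums(cnt[idx9[2L, ], , drop = FALSE]),
              colSums(cnt[idx9[3L, ], , drop = FALSE]))
  c3 <- rbind(colSums(cnt[idx9[, 1L], , drop = FALSE]),
              colSums(cnt[idx9[, 2L], , drop = FALSE]),
              colSums(cnt[idx9[, 3L], , drop = FALSE]))
  p_exp <- colSums(r3 * (w %*% c3)) / n^2
  est <- (p_obs - p_exp) / (1 - p_exp)
  est[1 - p_exp < tol] <- NA_real_
  est
}

# One shared resample of trial indices applied to every cell stream.
# cells_list: list of integer vectors (all length n). Returns a B x S
# matrix of kappa replicates (NA = not estimable replicate).
boot_kappa_streams <- function(cells_list, n, B, w) {
  idx <- sample.int(n, n * B, replace = TRUE)
  off <- rep(0:(B - 1L), each = n) * 9L
  out <- matrix(NA_real_, B, length(cells_list))
  for (s in seq_along(cells_list)) {
    cnt <- matrix(tabulate(off + cells_list[[s]][idx], 9L * B), 9L, B)
    out[, s] <- kappa_cols(cnt, w)
  }
  out
}

# Leave-one-trial-out kappas from a cell vector (memoised over the at most
# nine distinct cells a removed trial can occupy).
jackknife_kappa <- function(cells, w) {
  cnt <- tabulate(cells, 9L)
  present <- sort(unique(cells))
  loo <- vapply(present, function(cell) {
    ct <- cnt
    ct[cell] <- ct[cell] - 1L
    kappa_cols(matrix(ct, 9L, 1L), w)
  }, numeric(1L))
  loo[match(cells, present)]
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Reads a two-sided `1 - alpha` BCa interval off an empirical replicate
#' distribution. The bias correction is
#' \eqn{z_0 = \Phi^{-1}[(\#\{\theta^* < \hat\theta\} +
#' \frac12\#\{\theta^* = \hat\theta\})/B]} (replicates tied with the point
#' estimate count half, avoiding \eqn{\Phi^{-1}(0)} in degenerate streams)
#' and the acceleration is the jackknife skewness
#' \eqn{a = \sum(\bar\theta - \theta_i)^3 / (6[\sum(\bar\theta -
#' \theta_i)^2]^{3/2})}. The adjusted percentile levels are
#' \eqn{\Phi(z_0 + (z_0 + z_{\alpha/2})/(1 - a(z_0 + z_{\alpha/2})))} and
#' the mirrored upper form.
#'
#' @param replicates Numeric vector of bootstrap replicates (NAs dropped).
#' @param point_estimate The statistic on the original data.
#' @param jackknife_values Leave-one-out statistics on the original data.
#' @param alpha Two-sided level (default 0.05 for a 95\% interval).
#' @return Numeric `c(low, high)` with attributes `z0`, `a`, and
#'   `degenerate` (TRUE when all replicates are identical, in which case
#'   the interval collapses to the point estimate) .
#' @export
bca_interval <- function(replicates, point_estimate, jackknife_values,
                         alpha = 0.05) {
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (B < 100) stop("need >= 100 finite replicates", call. = FALSE)
  jackknife_values <- jackknife_values[is.finite(jackknife_values)]
  if (length(jackknife_values) < 3) {
    stop("need >= 3 jackknife values", call. = FALSE)
  }
  check_boot_settings(B, alpha)
  if (max(replicates) - min(replicates) == 0) {
    out <- c(point_estimate, point_estimate)
    attr(out, "z0") <- 0
    attr(out, "a") <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  za <- bca_z0_a(replicates, point_estimate, jackknife_values)
  out <- bca_endpoints(sort(replicates), za$z0, za$a, alpha)
  attr(out, "z0") <- za$z0
  attr(out, "a") <- za$a
  attr(out, "degenerate") <- FALSE
  out
}

bca_z0_a <- function(replicates, t0, jack) {
  jack <- jack[is.finite(jack)]
  B <- length(replicates)
  prop <- (sum(replicates < t0) + 0.5 * sum(replicates == t0)) / B
  prop <- min(max(prop, 0.5 / B), 1 - 0.5 / B)  # keep z0 finite
  z0 <- stats::qnorm(prop)
  d <- mean(jack) - jack
  s2 <- sum(d^2)
  a <- if (s2 > 0) sum(d^3) / (6 * s2^1.5) else 0
  list(z0 = z0, a = a)
}

bca_endpoints <- function(sorted_reps, z0, a, alpha) {
  zl <- stats::qnorm(alpha / 2)
  zu <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  unname(stats::quantile(sorted_reps, c(a1, a2), names = FALSE))
}

# Two-sided p by CI inversion: smallest alpha at which the (1 - alpha) BCa
# interval excludes zero, located by bisection to tolerance 1/B.
bca_pvalue <- function(replicates, t0, jack) {
  replicates <- replicates[is.finite(replicates)]
  B <- length(replicates)
  if (max(replicates) - min(replicates) == 0) {
    return(if (t0 == 0) 1 else 1 / B)
  }
  za <- bca_z0_a(replicates, t0, jack)
  sr <- sort(replicates)
  excludes <- function(alpha) {
    e <- bca_endpoints(sr, za$z0, za$a, alpha)
    e[1L] > 0 || e[2L] < 0
  }
  lo <- 1 / B
  hi <- 1 - 1 / B
  if (!excludes(hi)) return(1)
  if (excludes(lo)) return(lo)
  while (hi - lo > 1 / B) {
    mid <- (lo + hi) / 2
    if (excludes(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Bootstrap a weighted kappa with a BCa confidence interval
#'
#' Resamples trials with replacement as intact rating pairs, recomputes the
#' weighted kappa per replicate, and attaches a BCa interval (acceleration
#' from leave-one-trial-out jackknife). Replicates in which the statistic
#' is not estimable are dropped and counted; if more than half the
#' replicates are dropped, or the point estimate itself is not estimable,
#' the whole result is flagged not estimable.
#'
#' @param ratings_a,ratings_b Named per-trial rating vectors for one
#'   domain (names = trial identifiers).
#' @param weights Agreement weight matrix, see [weight_matrix()].
#' @param n_replicates Bootstrap replicates B (default 2000).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Optional integer seed for reproducibility.
#' @return A `"wkappa"` object with elements `ci`, `alpha`,
#'   `n_replicates`, `n_dropped`, `degenerate` added.
#' @export
bootstrap_kappa <- function(ratings_a, ratings_b, weights = weight_matrix(),
                            n_replicates = 2000, alpha = 0.05, seed = NULL) {
  check_boot_settings(n_replicates, alpha)
  if (!is.null(seed)) set.seed(seed)
  common <- intersect(names(ratings_a), names(ratings_b))
  if (length(common) < 2) stop("need >= 2 common trials", call. = FALSE)
  cells <- pair_cells(ratings_a[common], ratings_b[common])
  n <- length(cells)
  res <- weighted_kappa(cells_to_table(cells), weights)
  res$alpha <- alpha
  res$n_replicates <- as.integer(n_replicates)
  if (!res$estimable) {
    res$ci <- c(NA_real_, NA_real_)
    res$n_dropped <- NA_integer_
    return(res)
  }
  reps <- boot_kappa_streams(list(cells), n, n_replicates, weights)[, 1L]
  dropped <- sum(is.na(reps))
  res$n_dropped <- dropped
  if (dropped > n_replicates / 2 || n_replicates - dropped < 100) {
    res$estimable <- FALSE
    res$estimate <- NA_real_
    res$band <- "NE"
    res$ci <- c(NA_real_, NA_real_)
    return(res)
  }
  jack <- jackknife_kappa(cells, weights)
  ci <- bca_interval(reps, res$estimate, jack, alpha)
  res$ci <- as.numeric(ci)
  res$degenerate <- attr(ci, "degenerate")
  res
}

# Join a comparison (list/pair of two named rating vectors) on a trial set.
join_comparison <- function(comp, trials) {
  list(a = comp[[1L]][trials], b = comp[[2L]][trials])
}

comparison_trials <- function(comp) {
  intersect(names(comp[[1L]]), names(comp[[2L]]))
}

#' Bootstrapped difference in kappa between two comparisons
#'
#' Computes \eqn{\Delta\kappa = \kappa_A - \kappa_B} for two rater
#' comparisons over the same trials, with a paired bootstrap: each
#' replicate draws one resample of trial indices and applies it to both
#' comparisons, preserving their correlation. The BCa interval and the
#' two-sided p-value (smallest level at which the BCa interval excludes
#' zero, by bisection) are read off the replicate distribution of
#' \eqn{\Delta\kappa^*}.
#'
#' @param comparison_a,comparison_b Each a list of two named per-trial
#'   rating vectors (the two raters, or a pair consensus and the reference
#'   consensus).
#' @inheritParams bootstrap_kappa
#' @return An object of class `"kappa_diff"`: `delta`, `kappa_a`,
#'   `kappa_b` (each a `"wkappa"`), `ci`, `p_two_sided`, `estimable`, `n`,
#'   `n_dropped`, `n_replicates`, `alpha`.
#' @export
kappa_difference <- function(comparison_a, comparison_b,
                             weights = weight_matrix(), n_replicates = 2000,
                             alpha = 0.05, seed = NULL) {
  check_boot_settings(n_replicates, alpha)
  if (!is.null(seed)) set.seed(seed)
  trials <- Reduce(intersect, list(
    comparison_trials(comparison_a), comparison_trials(comparison_b)
  ))
  if (length(trials) < 2) {
    stop("comparisons must share >= 2 trials", call. = FALSE)
  }
  ca <- join_comparison(comparison_a, trials)
  cb <- join_comparison(comparison_b, trials)
  cells_a <- pair_cells(ca$a, ca$b)
  cells_b <- pair_cells(cb$a, cb$b)
  n <- length(trials)
  ka <- weighted_kappa(cells_to_table(cells_a), weights)
  kb <- weighted_kappa(cells_to_table(cells_b), weights)
  out <- list(
    delta = NA_real_, kappa_a = ka, kappa_b = kb,
    ci = c(NA_real_, NA_real_), p_two_sided = NA_real_,
    estimable = FALSE, n = n, n_dropped = NA_integer_,
    n_replicates = as.integer(n_replicates), alpha = alpha
  )
  class(out) <- "kappa_diff"
  if (!ka$estimable || !kb$estimable) return(out)
  out$delta <- ka$estimate - kb$estimate
  reps <- boot_kappa_streams(list(cells_a, cells_b), n, n_replicates, weights)
  drep <- reps[, 1L] - reps[, 2L]
  dropped <- sum(is.na(drep))
  out$n_dropped <- dropped
  if (dropped > n_replicates / 2 || n_replicates - dropped < 100) return(out)
  jack <- jackknife_kappa(cells_a, weights) - jackknife_kappa(cells_b, weights)
  ci <- bca_interval(drep, out$delta, jack, alpha)
  out$ci <- as.numeric(ci)
  out$p_two_sided <- bca_pvalue(drep, out$delta, jack)
  out$estimable <- TRUE
  out$degenerate <- attr(ci, "degenerate")
  out
}

#' @export
print.kappa_diff <- function(x, digits = 3, ...) {
  cat("Difference in weighted kappa (paired bootstrap, n =", x$n,
      "trials)\n")
  if (x$estimable) {
    cat(sprintf("  delta = %.*f  (kappa_A = %.*f, kappa_B = %.*f)\n",
                digits, x$delta, digits, x$kappa_a$estimate, digits,
                x$kappa_b$estimate))
    cat(sprintf("  %d%% BCa CI: (%.*f, %.*f); two-sided p = %s\n",
                round(100 * (1 - x$alpha)), digits, x$ci[1L], digits,
                x$ci[2L], format.pval(x$p_two_sided, digits = 2)))
  } else {
    cat("  NE (not estimable)\n")
  }
  invisible(x)
}

#' Stratified interaction test on a kappa difference
#'
#' Tests whether the difference in kappa between two comparisons differs
#' across the two levels of a stratifier (e.g. publication before/after
#' CONSORT 2010, or small/large trials). The interaction statistic is
#' \eqn{\Delta\kappa_{level_1} - \Delta\kappa_{level_2}}, with both
#' per-level deltas computed on the same replicate; resampling is
#' stratified (trials are resampled within their own level).
#'
#' @param comparisons_by_level Named list with exactly two elements (the
#'   stratum levels), each itself a list of two comparisons
#'   `list(comparison_a, comparison_b)` as in [kappa_difference()].
#' @param variable Optional label for the stratifying variable.
#' @inheritParams bootstrap_kappa
#' @return An object of class `"kappa_interaction"`: `variable`,
#'   `delta_by_level`, `interaction`, `ci`, `p_two_sided`, `estimable`.
#'   A level with fewer than 2 trials, or any not-estimable point kappa,
#'   yields a not-estimable ("NE") result.
#' @export
interaction_test <- function(comparisons_by_level, weights = weight_matrix(),
                             n_replicates = 2000, alpha = 0.05, seed = NULL,
                             variable = NULL) {
  check_boot_settings(n_replicates, alpha)
  if (length(comparisons_by_level) != 2L) {
    stop("exactly two stratum levels are required", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  levels <- names(comparisons_by_level)
  if (is.null(levels)) levels <- c("level1", "level2")
  out <- list(
    variable = variable, levels = levels,
    delta_by_level = stats::setNames(c(NA_real_, NA_real_), levels),
    interaction = NA_real_, ci = c(NA_real_, NA_real_),
    p_two_sided = NA_real_, estimable = FALSE,
    n_by_level = stats::setNames(c(NA_integer_, NA_integer_), levels),
    n_replicates = as.integer(n_replicates), alpha = alpha
  )
  class(out) <- "kappa_interaction"

  per_level <- vector("list", 2L)
  for (l in 1:2) {
    cmp <- comparisons_by_level[[l]]
    trials <- Reduce(intersect, list(
      comparison_trials(cmp[[1L]]), comparison_trials(cmp[[2L]])
    ))
    out$n_by_level[l] <- length(trials)
    if (length(trials) < 2) return(out)
    ca <- join_comparison(cmp[[1L]], trials)
    cb <- join_comparison(cmp[[2L]], trials)
    cells_a <- pair_cells(ca$a, ca$b)
    cells_b <- pair_cells(cb$a, cb$b)
    ka <- kappa_from_table(cells_to_table(cells_a), weights)
    kb <- kappa_from_table(cells_to_table(cells_b), weights)
    if (!ka$estimable || !kb$estimable) return(out)
    out$delta_by_level[l] <- ka$estimate - kb$estimate
    per_level[[l]] <- list(cells_a = cells_a, cells_b = cells_b,
                           n = length(trials))
  }
  out$interaction <- out$delta_by_level[1L] - out$delta_by_level[2L]

  # stratified resampling: independent index draws within each level,
  # shared between the two comparisons of that level
  drep <- matrix(NA_real_, n_replicates, 2L)
  for (l in 1:2) {
    pl <- per_level[[l]]
    reps <- boot_kappa_streams(list(pl$cells_a, pl$cells_b), pl$n,
                               n_replicates, weights)
    drep[, l] <- reps[, 1L] - reps[, 2L]
  }
  irep <- drep[, 1L] - drep[, 2L]
  dropped <- sum(is.na(irep))
  out$n_dropped <- dropped
  if (dropped > n_replicates / 2 || n_replicates - dropped < 100) return(out)

  # jackknife: leave one trial out of its own level
  jack <- unlist(lapply(1:2, function(l) {
    pl <- per_level[[l]]
    dj <- jackknife_kappa(pl$cells_a, weights) -
      jackknife_kappa(pl$cells_b, weights)
    d_other <- out$delta_by_level[3L - l]
    if (l == 1L) dj - d_other else out$delta_by_level[1L] - dj
  }))
  ci <- bca_interval(irep, unname(out$interaction), jack, alpha)
  out$ci <- as.numeric(ci)
  out$p_two_sided <- bca_pvalue(irep, unname(out$interaction), jack)
  out$estimable <- TRUE
  out$degenerate <- attr(ci, "degenerate")
  out
}

#' @export
print.kappa_interaction <- function(x, digits = 3, ...) {
  cat("Kappa-difference interaction",
      if (!is.null(x$variable)) paste0("(", x$variable, ")"), "\n")
  if (x$estimable) {
    cat(sprintf("  delta[%s] = %.*f, delta[%s] = %.*f\n",
                x$levels[1L], digits, x$delta_by_level[1L],
                x$levels[2L], digits, x$delta_by_level[2L]))
    cat(sprintf("  interaction = %.*f, %d%% BCa CI (%.*f, %.*f), p = %s\n",
                digits, x$interaction, round(100 * (1 - x$alpha)),
                digits, x$ci[1L], digits, x$ci[2L],
                format.pval(x$p_two_sided, digits = 2)))
  } else {
    cat("  NE (not estimable)\n")
  }
  invisible(x)
}
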