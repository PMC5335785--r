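# Synthetic reliability studies: latent true ratings per (trial, domain),
# noisy raters defined by confusion matrices, pair consensus with a
# fidelity parameter, and an analytic expected-kappa oracle. Trials and
# domains are i.i.d. -- a deliberate simplification of real trial data
# (no within-trial correlation of domains, no rater learning).

#' Rater profile: confusion matrix
#'
#' A rater is a 3x3 row-stochastic confusion matrix: row = latent true
#' rating, column = reported rating.
#'
#' @param confusion 3x3 numeric matrix with nonnegative entries and rows
#'   summing to 1 (within 1e-9).
#' @return The validated matrix with rating-level dimnames, class
#'   `"rater_profile"`.
#' @export
rater_profile <- function(confusion) {
  confusion <- unname(as.matrix(confusion))
  if (!identical(dim(confusion), c(3L, 3L)) || !is.numeric(confusion)) {
    stop("confusion must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (any(confusion < 0) || any(!is.finite(confusion))) {
    stop("confusion entries must be nonnegative and finite", call. = FALSE)
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion rows must sum to 1", call. = FALSE)
  }
  dimnames(confusion) <- list(RATING_LEVELS, RATING_LEVELS)
  structure(confusion, class = c("rater_profile", "matrix"))
}

#' Symmetric-accuracy rater profile
#'
#' Convenience constructor: probability `accuracy` of reporting the true
#' category, with the remaining mass split evenly over the other two.
#' `accuracy = 1` is a perfect rater; `accuracy = 1/3` reports at random.
#'
#' @param accuracy Probability in \[1/3, 1\].
#' @return A [rater_profile()].
#' @export
accuracy_profile <- function(accuracy) {
  if (accuracy < 0 || accuracy > 1) {
    stop("accuracy must lie in [0, 1]", call. = FALSE)
  }
  off <- (1 - accuracy) / 2
  m <- matrix(off, 3L, 3L)
  diag(m) <- accuracy
  rater_profile(m)
}

#' Default per-domain truth marginals
#'
#' Consensus rating proportions of the six bias domains in a 56-trial
#' risk-of-bias study of physical-therapy randomized trials, used as the
#' default template for the latent truth distribution.
#'
#' @return 6x3 matrix of probabilities (domains x rating levels), rows
#'   summing to 1.
#' @export
default_marginals <- function() {
  counts <- matrix(c(
    29, 27, 0,    # sequence_generation
    13, 42, 1,    # allocation_concealment
    16, 7, 33,    # blinding_patients
    4, 1, 51,     # blinding_therapists
    22, 12, 22,   # blinding_assessors
    17, 13, 26    # incomplete_outcome_data
  ), nrow = 6L, byrow = TRUE,
  dimnames = list(BIAS_DOMAINS, RATING_LEVELS))
  counts / rowSums(counts)
}

#' Scenario configuration for a synthetic reliability study
#'
#' Describes a complete generative reliability study: latent truth
#' marginals per domain, one confusion-matrix profile per rater in each of
#' the three groups (two inexperienced pairs -- minimal and intensive
#' training -- and one experienced reference pair), a consensus fidelity
#' per group, samplers for trial metadata, and a seed.
#'
#' Defaults emulate the study conditions: 56 trials, six domains with the
#' [default_marginals()] truth template, minimal-training raters with
#' diagonal accuracy 0.60, intensive-training and reference raters with
#' accuracy 0.95, consensus fidelity 0.6 (minimal) / 0.9 (intensive,
#' reference), publication years uniform on 1995--2013, and smallest-arm
#' sizes lognormal (median 32) truncated below at 10.
#'
#' @param n_trials Number of trials.
#' @param marginals 6x3 matrix of per-domain truth marginals (rows sum
#'   to 1), or a single length-3 probability vector recycled to all
#'   domains.
#' @param profiles Named list (`minimal`, `intensive`, `reference`), each
#'   a list of exactly two [rater_profile()]s.
#' @param fidelity Named numeric vector of per-group consensus fidelities
#'   in \[0, 1\]: the probability that a within-pair disagreement resolves
#'   to the latent true rating (otherwise uniformly to one of the two
#'   raters' answers).
#' @param year_sampler Function `n -> integer years`.
#' @param arm_sampler Function `n -> integer smallest-arm sizes`.
#' @param seed Integer seed.
#' @return An object of class `"rob_scenario"`.
#' @export
scenario_config <- function(n_trials = 56,
                            marginals = default_marginals(),
                            profiles = list(
                              minimal = list(accuracy_profile(0.60),
                                             accuracy_profile(0.60)),
                              intensive = list(accuracy_profile(0.95),
                                               accuracy_profile(0.95)),
                              reference = list(accuracy_profile(0.95),
                                               accuracy_profile(0.95))
                            ),
                            fidelity = c(minimal = 0.6, intensive = 0.9,
                                         reference = 0.9),
                            year_sampler = function(n)
                              sample(1995:2013, n, replace = TRUE),
                            arm_sampler = function(n)
                              pmax(10L, as.integer(round(
                                stats::rlnorm(n, log(32), 0.6)))),
                            seed = 1L) {
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials)) {
    stop("n_trials must be a positive integer", call. = FALSE)
  }
  if (is.null(dim(marginals))) {
    marginals <- matrix(rep(marginals, each = 6L), 6L, 3L,
                        dimnames = list(BIAS_DOMAINS, RATING_LEVELS))
  }
  marginals <- as.matrix(marginals)
  if (!identical(dim(marginals), c(6L, 3L))) {
    stop("marginals must be a 6x3 matrix (domains x rating levels)",
         call. = FALSE)
  }
  if (any(marginals < 0) || any(abs(rowSums(marginals) - 1) > 1e-9)) {
    stop("each domain's marginals must be nonnegative and sum to 1",
         call. = FALSE)
  }
  rownames(marginals) <- BIAS_DOMAINS
  colnames(marginals) <- RATING_LEVELS
  if (!setequal(names(profiles), RATER_GROUPS)) {
    stop("profiles must name exactly the groups {",
         paste(RATER_GROUPS, collapse = ", "), "}", call. = FALSE)
  }
  for (g in RATER_GROUPS) {
    if (length(profiles[[g]]) != 2L) {
      stop("each group must have exactly 2 rater profiles", call. = FALSE)
    }
    profiles[[g]] <- lapply(profiles[[g]], rater_profile)
  }
  if (!setequal(names(fidelity), RATER_GROUPS) ||
      any(fidelity < 0) || any(fidelity > 1)) {
    stop("fidelity must be named per group, each in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_trials = as.integer(n_trials), marginals = marginals,
    profiles = profiles, fidelity = fidelity,
    year_sampler = year_sampler, arm_sampler = arm_sampler,
    seed = as.integer(seed)
  ), class = "rob_scenario")
}

#' @export
print.rob_scenario <- function(x, ...) {
  cat("Synthetic reliability scenario:", x$n_trials, "trials x",
      nrow(x$marginals), "domains\n")
  cat("  groups:", paste(RATER_GROUPS, collapse = ", "),
      "(2 raters each)\n")
  cat("  consensus fidelity:",
      paste(sprintf("%s=%.2f", names(x$fidelity), x$fidelity),
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate latent true ratings and trial metadata
#'
#' Draws one latent true rating per (trial, domain) independently from the
#' domain's marginal distribution, and trial metadata from the configured
#' samplers.
#'
#' @param config A [scenario_config()].
#' @param seed Optional seed; defaults to `config$seed`. Pass `NA` to use
#'   the current RNG state.
#' @return List with `truth` (data.frame `trial_id, domain, rating`) and
#'   `meta` (data.frame `trial_id, publication_year, min_per_arm`).
#' @export
simulate_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rob_scenario"))
  if (!is.na(seed)) set.seed(seed)
  n <- config$n_trials
  trial_ids <- sprintf("T%03d", seq_len(n))
  truth <- expand.grid(trial_id = trial_ids, domain = BIAS_DOMAINS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$rating <- NA_character_
  for (d in BIAS_DOMAINS) {
    sel <- truth$domain == d
    truth$rating[sel] <- sample(RATING_LEVELS, n, replace = TRUE,
                                prob = config$marginals[d, ])
  }
  truth$rating <- factor(truth$rating, levels = RATING_LEVELS)
  truth$domain <- factor(truth$domain, levels = BIAS_DOMAINS)
  meta <- data.frame(
    trial_id = trial_ids,
    publication_year = as.integer(config$year_sampler(n)),
    min_per_arm = as.integer(config$arm_sampler(n))
  )
  list(truth = truth, meta = validate_trial_meta(meta))
}

#' Simulate one rater's reported ratings
#'
#' Each reported rating is drawn from the confusion-matrix row of the
#' latent true rating.
#'
#' @param truth Data.frame `trial_id, domain, rating` of latent ratings.
#' @param profile A [rater_profile()].
#' @param assessor_id,group Identifiers recorded on the output.
#' @param seed Optional seed (`NULL` = current RNG state).
#' @return Data.frame of individual-stage rating records.
#' @export
simulate_rater <- function(truth, profile, assessor_id = "rater",
                           group = "minimal", seed = NULL) {
  profile <- rater_profile(profile)
  if (!is.null(seed)) set.seed(seed)
  ti <- as.integer(as_rating(truth$rating))
  u <- stats::runif(length(ti))
  cum <- t(apply(unclass(profile), 1L, cumsum))
  reported <- 1L + (u > cum[cbind(ti, 1L)]) + (u > cum[cbind(ti, 2L)])
  data.frame(
    trial_id = truth$trial_id,
    domain = truth$domain,
    assessor_id = assessor_id,
    group = group,
    stage = "individual",
    rating = factor(RATING_LEVELS[reported], levels = RATING_LEVELS)
  )
}

#' Simulate a pair's consensus ratings
#'
#' Where the two raters agree, the consensus is the agreed rating. Where
#' they disagree, the discussion resolves to the latent true rating with
#' probability `fidelity`, and otherwise uniformly to one of the two
#' raters' answers.
#'
#' @param ratings_a,ratings_b Individual rating records of the two raters
#'   (same trial/domain coverage).
#' @param truth Latent ratings data.frame.
#' @param fidelity Probability in \[0, 1\].
#' @param assessor_id,group Identifiers recorded on the output.
#' @param seed Optional seed.
#' @return Data.frame of consensus-stage rating records.
#' @export
simulate_consensus <- function(ratings_a, ratings_b, truth, fidelity,
                               assessor_id = "pair", group = "minimal",
                               seed = NULL) {
  if (fidelity < 0 || fidelity > 1) {
    stop("fidelity must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  key <- function(df) paste(df$trial_id, df$domain, sep = "\r")
  ka <- key(ratings_a); kb <- key(ratings_b); kt <- key(truth)
  if (!setequal(ka, kb) || anyDuplicated(ka)) {
    stop("rater inputs must cover the same (trial, domain) set exactly once",
         call. = FALSE)
  }
  b <- ratings_b[match(ka, kb), ]
  tr <- truth[match(ka, kt), ]
  if (anyNA(tr$rating)) {
    stop("truth must cover every (trial, domain) of the raters",
         call. = FALSE)
  }
  ra <- as_rating(ratings_a$rating)
  rb <- as_rating(b$rating)
  rt <- as_rating(tr$rating)
  cons <- ra
  dis <- which(ra != rb)
  if (length(dis)) {
    to_truth <- stats::runif(length(dis)) < fidelity
    pick_a <- stats::runif(length(dis)) < 0.5
    cons[dis] <- ifelse(to_truth, as.character(rt[dis]),
                        ifelse(pick_a, as.character(ra[dis]),
                               as.character(rb[dis])))
  }
  data.frame(
    trial_id = ratings_a$trial_id,
    domain = ratings_a$domain,
    assessor_id = assessor_id,
    group = group,
    stage = "consensus",
    rating = factor(cons, levels = RATING_LEVELS)
  )
}

#' Analytic expected weighted kappa for a rater pair
#'
#' For truth marginal `m` and confusion matrices `A`, `B`, the joint
#' reporting distribution is \eqn{P_{ab}(i,j) = \sum_t m(t) A(t,i) B(t,j)}.
#' The expected weighted kappa applies the observed/chance-agreement
#' formulas to `P` directly. This is the analytic oracle against which
#' simulated kappas converge at large n.
#'
#' @param marginals Length-3 probability vector over the rating levels.
#' @param profile_a,profile_b [rater_profile()]s.
#' @param weights Agreement weight matrix.
#' @return Expected kappa (scalar); `NA` when chance-expected agreement
#'   is 1 (not estimable, e.g. a point-mass marginal with perfect raters).
#' @export
expected_kappa <- function(marginals, profile_a, profile_b,
                           weights = weight_matrix()) {
  if (length(marginals) != 3L || any(marginals < 0) ||
      abs(sum(marginals) - 1) > 1e-9) {
    stop("marginals must be a length-3 probability vector", call. = FALSE)
  }
  a <- unclass(rater_profile(profile_a))
  b <- unclass(rater_profile(profile_b))
  validate_weight_matrix(weights)
  p <- t(a) %*% (marginals * b)   # P[i, j] = sum_t m_t A[t,i] B[t,j]
  kappa_from_table(p, weights)$estimate
}

#' Tune rater accuracy to a target expected kappa
#'
#' Solves for the diagonal accuracy of a symmetric [accuracy_profile()]
#' pair whose analytic [expected_kappa()] under the given truth marginal
#' equals `target`.
#'
#' @param target Target kappa in (0, 1).
#' @param marginals Length-3 truth probability vector.
#' @param weights Agreement weight matrix.
#' @return Accuracy in (1/3, 1).
#' @export
tune_accuracy <- function(target, marginals, weights = weight_matrix()) {
  if (target <= 0 || target >= 1) {
    stop("target kappa must lie in (0, 1)", call. = FALSE)
  }
  f <- function(p) {
    expected_kappa(marginals, accuracy_profile(p), accuracy_profile(p),
                   weights) - target
  }
  stats::uniroot(f, c(1 / 3 + 1e-6, 1 - 1e-9), tol = 1e-10)$root
}

#' Build a complete synthetic reliability study
#'
#' Generates latent truth and metadata, individual ratings for the four
#' inexperienced raters and the two reference raters, and pair consensus
#' for all three pairs; optionally writes the two CSVs of the ratings
#' schema.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory: writes `ratings.csv` and `meta.csv`.
#' @param seed Optional seed; defaults to `config$seed`.
#' @return List with `ratings` (all individual + consensus records),
#'   `meta`, `truth`, and (if `dir` given) `paths`.
#' @export
build_scenario <- function(config, dir = NULL, seed = config$seed) {
  stopifnot(inherits(config, "rob_scenario"))
  if (!is.na(seed)) set.seed(seed)
  sim <- simulate_truth(config, seed = NA)
  records <- list()
  for (g in RATER_GROUPS) {
    indiv <- lapply(1:2, function(r) {
      simulate_rater(sim$truth, config$profiles[[g]][[r]],
                     assessor_id = paste0(g, "_r", r), group = g)
    })
    cons <- simulate_consensus(indiv[[1L]], indiv[[2L]], sim$truth,
                               fidelity = config$fidelity[[g]],
                               assessor_id = paste0(g, "_pair"), group = g)
    records <- c(records, indiv, list(cons))
  }
  ratings <- validate_ratings(do.call(rbind, records))
  out <- list(ratings = ratings, meta = sim$meta, truth = sim$truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rp <- file.path(dir, "ratings.csv")
    mp <- file.path(dir, "meta.csv")
    write_ratings(ratings, rp)
    utils::write.csv(sim$meta, mp, row.names = FALSE, quote = FALSE)
    out$paths <- c(ratings = rp, meta = mp)
  }
  out
}

#' @export
#' @rdname build_scenario
#' @param object,nsim,... For the [stats::simulate()] method: the
#'   scenario, the number of studies to generate, unused extras.
simulate.rob_scenario <- function(object, nsim = 1, seed = object$seed,
                                  ...) {
  if (!is.na(seed)) set.seed(seed)
  replicate(nsim, build_scenario(object, seed = NA), simplify = FALSE)
}
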