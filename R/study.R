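# Full-study orchestration: between-group reliability (pair consensus vs
# reference consensus, the primary outcome), within-group reliability (the
# two individual raters of each inexperienced pair, the secondary
# outcome), bootstrapped group differences (always intensive - minimal),
# stratified interactions, and Table-1-style tabulation.

# named per-trial rating vector for one domain from a record subset
ratings_vector <- function(df, d) {
  sub <- df[df$domain == d, , drop = FALSE]
  stats::setNames(as.character(sub$rating), sub$trial_id)
}

#' Run the full reliability study
#'
#' Computes, for every bias domain present in the ratings: between-group
#' kappa (each inexperienced pair's consensus vs the reference pair's
#' consensus) and within-group kappa (the two individual raters of each
#' inexperienced pair), each with a BCa bootstrap interval; the
#' bootstrapped difference in kappa between training groups (oriented
#' intensive - minimal, so positive values favor standardized training)
#' for both designs; and, when trial metadata are supplied, interaction
#' tests of the between-group difference across the publication-period and
#' trial-size strata.
#'
#' @param ratings Rating records (data.frame as from [read_ratings()] or
#'   [build_scenario()]): consensus-stage records for the minimal,
#'   intensive and reference pairs, and individual-stage records for the
#'   four inexperienced raters.
#' @param meta Optional trial metadata (from [read_trial_meta()]);
#'   required for the stratified interaction tests.
#' @param weights Agreement weight matrix, see [weight_matrix()].
#' @param n_replicates,alpha Bootstrap settings.
#' @param seed Integer seed; the whole study consumes one seeded RNG
#'   stream, so identical inputs and seed give bit-identical results.
#' @return An object of class `"rob_study"`.
#' @export
run_study <- function(ratings, meta = NULL, weights = weight_matrix(),
                      n_replicates = 2000, alpha = 0.05, seed = 1L) {
  check_boot_settings(n_replicates, alpha)
  ratings <- validate_ratings(as.data.frame(ratings))
  set.seed(seed)

  cons <- ratings[ratings$stage == "consensus", , drop = FALSE]
  indiv <- ratings[ratings$stage == "individual", , drop = FALSE]
  for (g in RATER_GROUPS) {
    if (!any(cons$group == g)) {
      stop("missing consensus records for group '", g, "'", call. = FALSE)
    }
  }
  for (g in c("minimal", "intensive")) {
    n_raters <- length(unique(indiv$assessor_id[indiv$group == g]))
    if (n_raters != 2L) {
      stop("group '", g, "' must have individual records from exactly ",
           "2 raters (found ", n_raters, ")", call. = FALSE)
    }
  }
  domains <- intersect(BIAS_DOMAINS, unique(as.character(ratings$domain)))
  if (!is.null(meta)) meta <- assign_strata(meta)

  boot <- function(a, b) {
    bootstrap_kappa(a, b, weights, n_replicates, alpha, seed = NULL)
  }
  results <- lapply(domains, function(d) {
    cons_g <- lapply(stats::setNames(RATER_GROUPS, RATER_GROUPS),
                     function(g) {
      ratings_vector(cons[cons$group == g, , drop = FALSE], d)
    })
    pair_g <- lapply(stats::setNames(c("minimal", "intensive"),
                                     c("minimal", "intensive")),
                     function(g) {
      sub <- indiv[indiv$group == g, , drop = FALSE]
      ids <- sort(unique(sub$assessor_id))
      lapply(ids, function(a) {
        ratings_vector(sub[sub$assessor_id == a, , drop = FALSE], d)
      })
    })
    res <- list(domain = d)
    res$between <- list(
      minimal = boot(cons_g$minimal, cons_g$reference),
      intensive = boot(cons_g$intensive, cons_g$reference)
    )
    res$within <- list(
      minimal = boot(pair_g$minimal[[1L]], pair_g$minimal[[2L]]),
      intensive = boot(pair_g$intensive[[1L]], pair_g$intensive[[2L]])
    )
    res$diff_between <- kappa_difference(
      list(cons_g$intensive, cons_g$reference),
      list(cons_g$minimal, cons_g$reference),
      weights, n_replicates, alpha, seed = NULL
    )
    res$diff_within <- kappa_difference(
      pair_g$intensive, pair_g$minimal,
      weights, n_replicates, alpha, seed = NULL
    )
    if (!is.null(meta)) {
      res$interaction <- lapply(
        stats::setNames(c("publication_period", "trial_size"),
                        c("publication_period", "trial_size")),
        function(v) {
          by_level <- lapply(split(meta$trial_id, meta[[v]]), function(ids) {
            keep <- function(x) x[intersect(names(x), ids)]
            list(
              list(keep(cons_g$intensive), keep(cons_g$reference)),
              list(keep(cons_g$minimal), keep(cons_g$reference))
            )
          })
          interaction_test(by_level, weights, n_replicates, alpha,
                           seed = NULL, variable = v)
        }
      )
    }
    res
  })
  names(results) <- domains

  ref_cons <- cons[cons$group == "reference", , drop = FALSE]
  structure(list(
    domains = domains, results = results,
    tabulation = tabulate_consensus(ref_cons),
    n_trials = length(unique(ratings$trial_id)),
    settings = list(n_replicates = as.integer(n_replicates),
                    alpha = alpha, seed = as.integer(seed)),
    weights = weights
  ), class = "rob_study")
}

#' Tabulate consensus ratings per domain
#'
#' Counts the consensus ratings per (domain, level) and converts them to
#' integer percentages with round-half-up (so 12.5% prints as 13),
#' reproducing the layout of a per-domain risk-of-bias summary table.
#'
#' @param x Either a data.frame of consensus rating records (one per
#'   (trial, domain)), or a numeric matrix of counts (domains x 3 rating
#'   levels, rownames = domains).
#' @param n_trials Denominator for percentages; defaults to the number of
#'   distinct trials (records input) or the row sums (counts input).
#' @return Data.frame with columns `domain, rating, count, percent`.
#' @examples
#' tabulate_consensus(matrix(c(13, 42, 1), 1,
#'   dimnames = list("allocation_concealment", NULL)), n_trials = 56)
#' @export
tabulate_consensus <- function(x, n_trials = NULL) {
  if (is.matrix(x)) {
    counts <- x
    if (is.null(rownames(counts))) {
      stop("counts matrix needs domain rownames", call. = FALSE)
    }
    if (ncol(counts) != 3L) {
      stop("counts matrix must have 3 columns (low, unclear, high)",
           call. = FALSE)
    }
    if (is.null(n_trials)) n_trials <- rowSums(counts)
    n_trials <- rep_len(n_trials, nrow(counts))
  } else {
    df <- as.data.frame(x)
    if (nrow(df) == 0L) stop("no consensus records to tabulate",
                             call. = FALSE)
    key <- paste(df$trial_id, df$domain, sep = "\r")
    if (anyDuplicated(key)) {
      stop("more than one consensus rating per (trial, domain)",
           call. = FALSE)
    }
    df$rating <- as_rating(df$rating)
    doms <- intersect(BIAS_DOMAINS, unique(as.character(df$domain)))
    counts <- t(vapply(doms, function(d) {
      table(df$rating[df$domain == d])
    }, numeric(3L)))
    rownames(counts) <- doms
    if (is.null(n_trials)) n_trials <- rowSums(counts)
    n_trials <- rep_len(n_trials, nrow(counts))
  }
  if (any(n_trials < 1)) stop("n_trials must be >= 1", call. = FALSE)
  out <- expand.grid(rating = RATING_LEVELS, domain = rownames(counts),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("domain", "rating")]
  out$count <- as.vector(t(counts))
  out$percent <- as.integer(floor(
    100 * out$count / rep(n_trials, each = 3L) + 0.5))
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.rob_study <- function(x, ...) {
  rows <- list()
  add <- function(domain, design, comparison, est, ci, band, p, estimable) {
    rows[[length(rows) + 1L]] <<- data.frame(
      domain = domain, design = design, comparison = comparison,
      kappa = est, ci_low = ci[1L], ci_high = ci[2L], band = band,
      p_value = p, estimable = estimable
    )
  }
  for (d in x$domains) {
    r <- x$results[[d]]
    for (g in c("minimal", "intensive")) {
      k <- r$between[[g]]
      add(d, "between", paste0(g, "_vs_reference"), k$estimate, k$ci,
          k$band, NA_real_, k$estimable)
      k <- r$within[[g]]
      add(d, "within", paste0("within_", g), k$estimate, k$ci, k$band,
          NA_real_, k$estimable)
    }
    dd <- r$diff_between
    add(d, "between", "intensive_minus_minimal", dd$delta, dd$ci, "",
        dd$p_two_sided, dd$estimable)
    dd <- r$diff_within
    add(d, "within", "intensive_minus_minimal", dd$delta, dd$ci, "",
        dd$p_two_sided, dd$estimable)
    for (it in r$interaction) {
      add(d, "interaction", it$variable, unname(it$interaction), it$ci, "",
          it$p_two_sided, it$estimable)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rob_study <- function(x, digits = 2, ...) {
  cat("Risk-of-bias reliability study:", x$n_trials, "trials,",
      length(x$domains), "domains, B =", x$settings$n_replicates, "\n\n")
  fmt <- function(v) ifelse(is.na(v), "NE", sprintf("%.*f", digits, v))
  for (d in x$domains) {
    r <- x$results[[d]]
    cat(d, "\n")
    cat(sprintf("  between: minimal %s, intensive %s, diff %s (p %s)\n",
                fmt(r$between$minimal$estimate),
                fmt(r$between$intensive$estimate),
                fmt(r$diff_between$delta),
                ifelse(is.na(r$diff_between$p_two_sided), "NE",
                       format.pval(r$diff_between$p_two_sided,
                                   digits = 2))))
    cat(sprintf("  within:  minimal %s, intensive %s, diff %s (p %s)\n",
                fmt(r$within$minimal$estimate),
                fmt(r$within$intensive$estimate),
                fmt(r$diff_within$delta),
                ifelse(is.na(r$diff_within$p_two_sided), "NE",
                       format.pval(r$diff_within$p_two_sided,
                                   digits = 2))))
  }
  invisible(x)
}

#' @export
summary.rob_study <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, tabulation = object$tabulation,
                 settings = object$settings), class = "summary.rob_study")
}

#' @export
print.summary.rob_study <- function(x, ...) {
  cat("Per-domain reliability results\n")
  print(x$table, digits = 3)
  cat("\nReference consensus tabulation (count, integer percent)\n")
  print(x$tabulation)
  invisible(x)
}
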