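#' Cross-tabulate two raters' ratings over common trials
#'
#' Joins two per-trial rating vectors on their trial identifiers and
#' returns the 3x3 contingency table over the full ordinal category space
#' (a category unused by both raters still contributes a zero row/column,
#' keeping weight indexing stable).
#'
#' @param ratings_a,ratings_b Named vectors (names = trial identifiers) of
#'   ratings in `{low, unclear, high}` (character or factor).
#' @return A 3x3 integer matrix of counts; rows index rater A, columns
#'   rater B, in ordinal order; `attr(, "n")` holds the number of common
#'   trials.
#' @examples
#' a <- c(T1 = "low", T2 = "unclear")
#' b <- c(T1 = "unclear", T2 = "unclear")
#' cross_tabulate(a, b)
#' @export
cross_tabulate <- function(ratings_a, ratings_b) {
  if (is.null(names(ratings_a)) || is.null(names(ratings_b))) {
    stop("rating vectors must be named by trial_id", call. = FALSE)
  }
  common <- intersect(names(ratings_a), names(ratings_b))
  if (length(common) == 0L) {
    stop("no common trials between the two rating sets", call. = FALSE)
  }
  a <- as_rating(ratings_a[common])
  b <- as_rating(ratings_b[common])
  if (anyNA(a) || anyNA(b)) {
    stop("missing ratings among common trials", call. = FALSE)
  }
  tab <- table(a, b, dnn = NULL)
  tab <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(RATING_LEVELS, RATING_LEVELS))
  attr(tab, "n") <- length(common)
  tab
}

# Core kappa computation from a 3x3 count (or probability) table.
# Returns list(estimate, p_obs, p_exp, estimable). Not-estimable when
# 1 - p_exp < tol (zero rating variance: all mass in one matched category).
kappa_from_table <- function(tab, w, tol = 1e-12) {
  n <- sum(tab)
  p <- tab / n
  p_obs <- sum(w * p)
  r <- rowSums(p)
  cc <- colSums(p)
  p_exp <- sum(w * outer(r, cc))
  if (1 - p_exp < tol) {
    return(list(estimate = NA_real_, p_obs = p_obs, p_exp = p_exp,
                estimable = FALSE))
  }
  list(estimate = (p_obs - p_exp) / (1 - p_exp), p_obs = p_obs,
       p_exp = p_exp, estimable = TRUE)
}

#' Chance-corrected weighted kappa
#'
#' Computes weighted Cohen's kappa
#' \deqn{\kappa_w = (p_{obs} - p_{exp}) / (1 - p_{exp})}
#' where \eqn{p_{obs} = \sum_{ij} w_{ij} f_{ij} / n} is the weighted
#' observed agreement and \eqn{p_{exp} = \sum_{ij} w_{ij} r_i c_j / n^2}
#' the weighted chance-expected agreement from the marginal totals
#' \eqn{r, c}. When the chance-expected agreement is 1 to within `tol`
#' (zero rating variance) the statistic is undefined and the result is
#' flagged not estimable ("NE").
#'
#' @param table 3x3 count matrix (rows rater A, columns rater B, ordinal
#'   order), e.g. from [cross_tabulate()].
#' @param weights 3x3 agreement weight matrix from [weight_matrix()].
#' @param tol Not-estimable tolerance on `1 - p_exp`.
#' @return An object of class `"wkappa"`: list with `estimate`, `p_obs`,
#'   `p_exp`, `n`, `band`, `estimable`, `weights`.
#' @examples
#' tab <- matrix(c(10, 2, 0, 2, 10, 2, 0, 2, 10), 3, 3, byrow = TRUE)
#' weighted_kappa(tab)
#' @seealso [classify_kappa()], [bootstrap_kappa()]
#' @export
weighted_kappa <- function(table, weights = weight_matrix(), tol = 1e-12) {
  table <- unname(as.matrix(table))
  if (!identical(dim(table), c(3L, 3L))) {
    stop("contingency table must be 3x3", call. = FALSE)
  }
  if (any(table < 0) || any(!is.finite(table))) {
    stop("contingency table must contain nonnegative finite counts",
         call. = FALSE)
  }
  n <- sum(table)
  if (n < 1) stop("contingency table must contain at least one count",
                  call. = FALSE)
  validate_weight_matrix(weights)
  k <- kappa_from_table(table, weights, tol)
  res <- list(
    estimate = k$estimate, p_obs = k$p_obs, p_exp = k$p_exp,
    n = n, band = classify_kappa(k$estimate), estimable = k$estimable,
    weights = weights
  )
  class(res) <- "wkappa"
  res
}

#' Classify a kappa estimate into interpretation bands
#'
#' Bands (closed at two-decimal resolution; the estimate is rounded to two
#' decimals before classification so the bands form a contiguous partition
#' of \[-1, 1\]):
#' \itemize{
#'   \item 0.93--1.00 excellent
#'   \item 0.81--0.92 very good
#'   \item 0.61--0.80 good
#'   \item 0.41--0.60 fair
#'   \item 0.21--0.40 slight
#'   \item 0.01--0.20 poor
#'   \item 0.00 or less: none
#' }
#'
#' @param estimate Kappa value in \[-1, 1\], or `NA` for a not-estimable
#'   statistic.
#' @return Band label; `"NE"` for not-estimable input. Vectorised.
#' @export
classify_kappa <- function(estimate) {
  vapply(estimate, function(k) {
    if (is.na(k)) return("NE")
    if (k < -1 - 1e-9 || k > 1 + 1e-9) {
      stop("kappa estimate must lie in [-1, 1]", call. = FALSE)
    }
    k2 <- round(k, 2)
    if (k2 >= 0.93) "excellent"
    else if (k2 >= 0.81) "very good"
    else if (k2 >= 0.61) "good"
    else if (k2 >= 0.41) "fair"
    else if (k2 >= 0.21) "slight"
    else if (k2 >= 0.01) "poor"
    else "none"
  }, character(1L))
}

#' @export
print.wkappa <- function(x, digits = 3, ...) {
  cat("Weighted kappa (n =", x$n, "trials)\n")
  if (x$estimable) {
    cat(sprintf("  kappa = %.*f  [%s agreement]\n", digits, x$estimate,
                x$band))
    if (!is.null(x$ci)) {
      cat(sprintf("  %d%% BCa CI: (%.*f, %.*f)  [B = %d%s]\n",
                  round(100 * (1 - x$alpha)), digits, x$ci[1L], digits,
                  x$ci[2L], x$n_replicates,
                  if (isTRUE(x$n_dropped > 0))
                    sprintf(", %d NE replicates dropped", x$n_dropped)
                  else ""))
    }
  } else {
    cat("  kappa = NE (not estimable: chance-expected agreement is 1)\n")
  }
  cat(sprintf("  p_obs = %.*f, p_exp = %.*f\n", digits, x$p_obs, digits,
              x$p_exp))
  invisible(x)
}

#' @export
coef.wkappa <- function(object, ...) c(kappa = object$estimate)

#' @export
confint.wkappa <- function(object, parm, level, ...) {
  if (is.null(object$ci)) {
    stop("no bootstrap confidence interval attached; use bootstrap_kappa()",
         call. = FALSE)
  }
  ci <- matrix(object$ci, 1L, 2L)
  a <- object$alpha
  dimnames(ci) <- list("kappa", sprintf("%.1f %%", 100 * c(a / 2, 1 - a / 2)))
  ci
}
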