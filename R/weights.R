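#' Agreement weight matrix for ordinal ratings
#'
#' Builds the 3x3 agreement weight matrix used to compute weighted kappa
#' over the ordinal rating space low < unclear < high. The default scheme,
#' `"cochrane_adjacent_0.8"`, gives complete agreement (main diagonal) a
#' weight of 1, ratings in adjacent categories a weight of 0.8, and
#' low-vs-high disagreements a weight of 0.
#'
#' Available schemes:
#' \describe{
#'   \item{cochrane_adjacent_0.8}{1 / 0.8 / 0 (default).}
#'   \item{identity}{1 on the diagonal, 0 elsewhere: unweighted kappa.}
#'   \item{linear}{`1 - |i - j| / 2`.}
#'   \item{quadratic}{`1 - (i - j)^2 / 4`.}
#'   \item{custom}{matrix supplied via `custom`; must be symmetric with a
#'     unit diagonal and entries in \[0, 1\].}
#' }
#'
#' @param scheme Scheme identifier, see above.
#' @param custom 3x3 numeric matrix, required when `scheme = "custom"`.
#' @return A 3x3 numeric matrix with dimnames over the rating levels.
#' @examples
#' weight_matrix()["low", "unclear"] # 0.8
#' @export
weight_matrix <- function(scheme = c("cochrane_adjacent_0.8", "identity",
                                     "linear", "quadratic", "custom"),
                          custom = NULL) {
  scheme <- match.arg(scheme)
  idx <- 0:2
  d <- abs(outer(idx, idx, "-"))
  w <- switch(scheme,
    cochrane_adjacent_0.8 = ifelse(d == 0, 1, ifelse(d == 1, 0.8, 0)),
    identity = ifelse(d == 0, 1, 0),
    linear = 1 - d / 2,
    quadratic = 1 - d^2 / 4,
    custom = {
      if (is.null(custom)) {
        stop("scheme 'custom' requires a 3x3 matrix via `custom`", call. = FALSE)
      }
      custom <- unname(as.matrix(custom))
      validate_weight_matrix(custom)
      custom
    }
  )
  w <- matrix(as.numeric(w), 3L, 3L,
              dimnames = list(RATING_LEVELS, RATING_LEVELS))
  w
}

validate_weight_matrix <- function(w) {
  if (!is.matrix(w) || !identical(dim(w), c(3L, 3L)) || !is.numeric(w)) {
    stop("weight matrix must be a numeric 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(diag(w) - 1) > 1e-12)) {
    stop("weight matrix must have 1 on the diagonal", call. = FALSE)
  }
  if (any(abs(w - t(w)) > 1e-12)) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  invisible(w)
}
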