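# Asymptotic test for the equality of coefficients of variation across k
# groups (Feltz & Miller). Used here because event frequencies and
# amplitudes show large within-group variation, and comparing CVs asks
# whether that *relative* variability differs between conditions.

#' Asymptotic test for equality of coefficients of variation
#'
#' For groups `i = 1..k` with `n_i` observations, sample mean `m_i` and
#' standard deviation `s_i`, the coefficient of variation is
#' `c_i = s_i / m_i`. With `m_i = n_i - 1` (degrees of freedom) and the
#' pooled `c = sum(m_i c_i) / sum(m_i)`, the statistic
#' `D = sum(m_i (c_i - c)^2) / (c^2 (0.5 + c^2))`
#' is asymptotically chi-squared with `k - 1` degrees of freedom under the
#' null of equal CVs. `D` is zero when all group CVs coincide and is
#' invariant to rescaling all observations.
#'
#' @param data Either a named list of numeric vectors (one per group), or a
#'   data frame together with `value` and `group` column names.
#' @param value,group Column names when `data` is a data frame.
#' @return A `cv_test` object: `statistic`, `df`, `p_value`, `k_groups` and
#'   the per-group `cvs` tibble. [tidy()] returns the per-group table,
#'   [glance()] the one-row test summary.
#' @export
#' @examples
#' cv_equality_test(list(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8, 10)))
cv_equality_test <- function(data, value = NULL, group = NULL) {
  if (is.data.frame(data)) {
    if (is.null(value) || is.null(group))
      abort("supply `value` and `group` column names for data-frame input.")
    groups <- split(data[[value]], data[[group]])
  } else if (is.list(data)) {
    groups <- data
    if (is.null(names(groups)))
      names(groups) <- paste0("group", seq_along(groups))
  } else {
    abort("`data` must be a data frame or a list of numeric vectors.")
  }
  k <- length(groups)
  if (k < 2) abort("at least 2 groups are required.")
  ns <- lengths(groups)
  if (any(ns < 2)) abort("every group needs n >= 2 observations.")
  means <- vapply(groups, mean, numeric(1))
  if (any(means == 0)) abort("a group mean of zero leaves its CV undefined.")
  sds <- vapply(groups, sd, numeric(1))
  cvs <- sds / means
  m <- ns - 1
  c_pool <- sum(m * cvs) / sum(m)
  D <- if (c_pool == 0) 0 else
    sum(m * (cvs - c_pool)^2) / (c_pool^2 * (0.5 + c_pool^2))
  p <- pchisq(D, df = k - 1, lower.tail = FALSE)
  structure(list(
    statistic = D, df = k - 1L, p_value = p, k_groups = k,
    pooled_cv = c_pool,
    cvs = tibble::tibble(group = names(groups), n = as.integer(ns),
                         mean = means, sd = sds, cv = cvs)),
    class = "cv_test")
}

#' @export
print.cv_test <- function(x, ...) {
  cat(sprintf("Asymptotic test for equality of coefficients of variation\n"))
  cat(sprintf("  k = %d groups, chi-squared = %.4g, df = %d, p = %.4g\n",
              x$k_groups, x$statistic, x$df, x$p_value))
  cat(sprintf("  group CVs: %s\n",
              paste(sprintf("%s=%.3g", x$cvs$group, x$cvs$cv), collapse = ", ")))
  invisible(x)
}

#' @method tidy cv_test
#' @export
tidy.cv_test <- function(x, ...) x$cvs

#' @method glance cv_test
#' @export
glance.cv_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 k_groups = x$k_groups, pooled_cv = x$pooled_cv)
}
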