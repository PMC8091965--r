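#' @title Repeated-measures statistics
#' @description
#' The statistical machinery used on the per-condition outcome metrics:
#' single-factor repeated-measures ANOVA, Bonferroni-corrected paired
#' comparisons, and least-squares linear regression with R-squared.
#' @name stats_module
NULL

# coerce a subjects x conditions input (matrix, wide data frame with an
# optional subject id column, or long data frame with subject/condition/
# value columns) into a plain numeric matrix
.condition_matrix <- function(m) {
  if (is.data.frame(m) && all(c("subject", "condition", "value") %in% names(m))) {
    wide <- tidyr::pivot_wider(
      m[, c("subject", "condition", "value")],
      names_from = "condition", values_from = "value"
    )
    out <- as.matrix(wide[, -1, drop = FALSE])
    rownames(out) <- as.character(wide$subject)
    m <- out
  } else if (is.data.frame(m)) {
    if ("subject" %in% names(m)) {
      rn <- as.character(m$subject)
      m <- as.matrix(m[, setdiff(names(m), "subject"), drop = FALSE])
      rownames(m) <- rn
    } else {
      m <- as.matrix(m)
    }
  }
  if (!is.matrix(m) || !is.numeric(m)) stop("cannot interpret input as a subjects x conditions matrix")
  if (any(!is.finite(m))) stop("condition matrix must be complete (no missing cells)")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 conditions")
  m
}

#' Single-factor repeated-measures ANOVA
#'
#' Classical within-subjects decomposition
#' `SS_total = SS_subjects + SS_conditions + SS_error`, with
#' `F = MS_conditions / MS_error` on `(k - 1)` and `(n - 1)(k - 1)`
#' degrees of freedom. No sphericity correction is applied by default;
#' set `gg = TRUE` for the Greenhouse-Geisser-adjusted p value.
#'
#' @param m Subjects x conditions values: a numeric matrix, a wide data
#'   frame (optional `subject` column), or a long data frame with columns
#'   `subject`, `condition`, `value`.
#' @param gg Apply the Greenhouse-Geisser sphericity correction.
#' @return An object of class `nmm_rm_anova` with fields `statistic` (F),
#'   `df_effect`, `df_error`, `p.value`, the sum-of-squares table, and a
#'   `degenerate` flag set when the error variance is zero (then `F = 0`,
#'   `p = 1` if the condition effect is also zero, else `p = 0`).
#' @examples
#' m <- matrix(rnorm(12), nrow = 4)
#' rm_anova(m)
#' @export
rm_anova <- function(m, gg = FALSE) {
  m <- .condition_matrix(m)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_e <- k - 1; df_r <- (n - 1) * (k - 1)
  eps_tol <- 1e-12 * max(ss_tot, 1)
  degenerate <- ss_err <= eps_tol
  if (degenerate) {
    if (ss_cond <= eps_tol) {
      f <- 0; pval <- 1
    } else {
      f <- Inf; pval <- 0
    }
  } else {
    f <- (ss_cond / df_e) / (ss_err / df_r)
    if (gg) {
      eps <- .gg_epsilon(m)
      pval <- stats::pf(f, eps * df_e, eps * df_r, lower.tail = FALSE)
    } else {
      pval <- stats::pf(f, df_e, df_r, lower.tail = FALSE)
    }
  }
  structure(
    list(
      statistic = f, df_effect = df_e, df_error = df_r, p.value = pval,
      ss = c(subjects = ss_subj, conditions = ss_cond, error = ss_err,
             total = ss_tot),
      n_subjects = n, n_conditions = k,
      degenerate = degenerate, gg = gg,
      epsilon = if (gg) .gg_epsilon(m) else NA_real_
    ),
    class = "nmm_rm_anova"
  )
}

# Greenhouse-Geisser epsilon from the double-centered covariance matrix
.gg_epsilon <- function(m) {
  k <- ncol(m)
  s <- stats::cov(m)
  cm <- diag(k) - 1 / k
  sc <- cm %*% s %*% cm
  sum(diag(sc))^2 / ((k - 1) * sum(sc^2))
}

#' @export
print.nmm_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%g, %g) = %.4g, p = %.4g%s\n",
    x$df_effect, x$df_error, x$statistic, x$p.value,
    if (x$degenerate) "  [degenerate: zero error variance]" else ""
  ))
  invisible(x)
}

#' @rdname rm_anova
#' @param x An `nmm_rm_anova` object.
#' @param ... Unused.
#' @export
tidy.nmm_rm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("conditions", "subjects", "error"),
    df = c(x$df_effect, x$n_subjects - 1, x$df_error),
    sumsq = unname(x$ss[c("conditions", "subjects", "error")]),
    meansq = c(x$ss[["conditions"]] / x$df_effect,
               x$ss[["subjects"]] / (x$n_subjects - 1),
               x$ss[["error"]] / x$df_error),
    statistic = c(x$statistic, NA, NA),
    p.value = c(x$p.value, NA, NA)
  )
}

#' @rdname rm_anova
#' @export
glance.nmm_rm_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df_effect, df.residual = x$df_error,
    p.value = x$p.value, n_subjects = x$n_subjects,
    n_conditions = x$n_conditions, degenerate = x$degenerate
  )
}

#' Bonferroni-corrected paired comparisons
#'
#' Two-sided paired t-tests for the requested condition pairs, with the
#' Bonferroni adjustment `p_adj = min(1, p * n_pairs)`. Intended as the
#' post hoc step after a significant [rm_anova()] main effect (the
#' significance gate is the caller's responsibility). Pairs whose
#' within-subject differences have zero variance are flagged and get
#' `p = NA`.
#'
#' @inheritParams rm_anova
#' @param pairs List of length-2 character vectors (condition names) or
#'   2-column matrix; default: all pairwise combinations.
#' @return A tibble: `a`, `b`, `estimate` (mean difference a - b),
#'   `statistic`, `df`, `p.value`, `p.adj`, `flag`.
#' @export
pairwise_bonferroni <- function(m, pairs = NULL) {
  m <- .condition_matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  if (is.null(pairs)) {
    cmb <- utils::combn(colnames(m), 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- m[, pr[1]]; b <- m[, pr[2]]
    d <- a - b
    if (stats::sd(d) == 0) {
      # degenerate paired test: identical columns carry no evidence of a
      # difference (p = 1); a constant nonzero difference is an exact one
      pv <- if (mean(d) == 0) 1 else 0
      return(tibble::tibble(
        a = pr[1], b = pr[2], estimate = mean(d), statistic = NA_real_,
        df = length(d) - 1, p.value = pv, p.adj = min(1, pv * n_pairs),
        flag = "zero-variance differences"
      ))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(
      a = pr[1], b = pr[2], estimate = unname(tt$estimate),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value, p.adj = min(1, tt$p.value * n_pairs),
      flag = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

#' Least-squares linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x` with the slope t-test p value and
#' `R^2 = 1 - SS_res / SS_tot`. The print method formats the fit in the
#' conventional `y = a*x + b` reporting style, quoting R-squared with a
#' tilde when the regression is not significant at `alpha`.
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must not be constant.
#' @param alpha Significance level for the reporting convention.
#' @return An object of class `nmm_lslr` with `slope`, `intercept`,
#'   `r.squared`, `p.value`, `n`.
#' @examples
#' fit <- lslr(1:5, c(1.1, 1.9, 3.2, 3.8, 5.1))
#' fit$r.squared
#' @export
lslr <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  if (stats::sd(y) == 0) {
    # y carries no variance: flat fit, nothing explained
    return(structure(
      list(slope = 0, intercept = y[1], r.squared = 0, p.value = 1,
           n = length(x), alpha = alpha),
      class = "nmm_lslr"
    ))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r.squared = sm$r.squared,
      p.value = sm$coefficients[2, 4],
      n = length(x), alpha = alpha
    ),
    class = "nmm_lslr"
  )
}

#' @export
print.nmm_lslr <- function(x, ...) {
  tilde <- if (x$p.value < x$alpha) "" else "~"
  cat(sprintf("y = %.3f× %s %.3f   (R² %s %.3f, p = %.4g, n = %d)\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              if (tilde == "") "=" else "~", x$r.squared, x$p.value, x$n))
  invisible(x)
}

#' @rdname lslr
#' @param x An `nmm_lslr` object (for the methods).
#' @param ... Unused.
#' @export
tidy.nmm_lslr <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname lslr
#' @export
glance.nmm_lslr <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, p.value = x$p.value,
    slope = x$slope, intercept = x$intercept, n = x$n
  )
}
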