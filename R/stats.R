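#' Multivariate outlier detection by Minimum Covariance Determinant
#'
#' Robust location and scatter are estimated by MCD (support fraction 0.75,
#' seeded deterministic subsampling); rows whose robust squared Mahalanobis
#' distance exceeds the chi-squared quantile at `alpha` for `ncol(X)` degrees
#' of freedom are flagged.
#'
#' @param X numeric matrix or data.frame of the model's variables, one row
#'   per participant; at least `2 * (ncol + 1)` complete rows.
#' @param alpha flagging quantile (default 0.975).
#' @param support_fraction MCD subset fraction (default 0.75).
#' @param seed integer seed controlling the MCD subsampling.
#' @return logical mask, TRUE = outlier; attribute `"distance"` holds the
#'   robust squared Mahalanobis distances.
#' @export
mcd_outliers <- function(X, alpha = 0.975, support_fraction = 0.75, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values among model variables")
  n <- nrow(X); d <- ncol(X)
  if (n < 2 * (d + 1)) stop("too few rows for MCD")
  h <- floor(support_fraction * n)
  fit <- local_seed(seed,
    tryCatch(MASS::cov.rob(X, method = "mcd", quantile.used = h),
             error = function(e) stop("MCD failed: ", conditionMessage(e))))
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(1, max(ev)))
    stop("singular robust scatter")
  d2 <- stats::mahalanobis(X, fit$center, fit$cov)
  mask <- d2 > stats::qchisq(alpha, df = d)
  attr(mask, "distance") <- d2
  mask
}

#' Hierarchical ordinary least-squares regression
#'
#' Fits a step-1 model (covariates only; intercept-only when `step1` is
#' empty) and a step-2 model adding the focal predictor, and reports the
#' incremental variance explained: final adjusted R-squared, change in
#' adjusted R-squared, the F-change test with its degrees of freedom and p
#' value, the standardized focal coefficient with 95% CI, and the omnibus F
#' p value of the final model.
#'
#' @param table data.frame with one row per participant.
#' @param dependent name of the dependent variable.
#' @param step1 character vector of step-1 covariate names (may be empty).
#' @param step2 name of the focal predictor added in step 2.
#' @param transform optional named character vector of per-variable monotone
#'   transforms (`"sqrt"`, `"log"`), applied before fitting.
#' @param outlier_seed seed for the MCD outlier screen; `NULL` skips outlier
#'   removal.
#' @param max_condition collinearity guard: error when the model matrix
#'   condition number exceeds this (default 1e8).
#' @return object of class `"stat_result"`.
#' @export
hierarchical_regression <- function(table, dependent, step1 = c("age", "sex"),
                                    step2, transform = NULL,
                                    outlier_seed = 1,
                                    max_condition = 1e8) {
  stopifnot(is.data.frame(table))
  vars <- c(dependent, step1, step2)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    stop("variables not in table: ", paste(missing_vars, collapse = ", "))
  if (step2 %in% step1) stop("focal predictor also appears in step 1")
  tab <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]

  for (v in names(transform)) {
    tab[[v]] <- switch(transform[[v]],
                       sqrt = sqrt(tab[[v]]),
                       log = log(tab[[v]]),
                       stop("unknown transform: ", transform[[v]]))
  }
  # two-level character/factor covariates (sex) become 0/1 indicators
  for (v in vars) {
    if (is.character(tab[[v]]) || is.factor(tab[[v]])) {
      f <- factor(tab[[v]])
      if (nlevels(f) != 2L) stop(v, " must have exactly 2 levels")
      tab[[v]] <- as.numeric(f) - 1
    }
  }

  removed <- integer(0)
  if (!is.null(outlier_seed)) {
    num <- as.matrix(tab)
    mask <- mcd_outliers(num, seed = outlier_seed)
    removed <- which(mask)
    if (length(removed)) tab <- tab[-removed, , drop = FALSE]
  }
  n <- nrow(tab)
  p2 <- length(step1) + 1L
  if (n <= p2 + 2L) stop("too few rows after outlier removal")

  f1 <- stats::as.formula(paste(dependent, "~",
                                if (length(step1)) paste(step1, collapse = " + ")
                                else "1"))
  f2 <- stats::as.formula(paste(dependent, "~",
                                paste(c(step1, step2), collapse = " + ")))
  m1 <- stats::lm(f1, data = tab)
  m2 <- stats::lm(f2, data = tab)
  if (kappa(stats::model.matrix(m2), exact = TRUE) > max_condition)
    stop("collinear predictors (condition number too large)")

  adj <- function(m) summary(m)$adj.r.squared
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  df_num <- 1L
  df_den <- m2$df.residual
  F_change <- ((rss1 - rss2) / df_num) / (rss2 / df_den)
  p_change <- stats::pf(F_change, df_num, df_den, lower.tail = FALSE)

  sm2 <- summary(m2)
  b <- stats::coef(m2)[[step2]]
  beta_std <- b * stats::sd(tab[[step2]]) / stats::sd(tab[[dependent]])
  ci <- stats::confint(m2, step2, level = 0.95)
  fstat <- sm2$fstatistic
  p_omnibus <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)

  structure(list(dependent = dependent, step1 = step1, step2 = step2,
                 n = n, outliers_removed = removed,
                 adj_r2_step1 = adj(m1), adj_r2_final = adj(m2),
                 delta_adj_r2 = adj(m2) - adj(m1),
                 F_change = F_change, df = c(df_num, df_den),
                 p_change = p_change,
                 beta_focal = beta_std, ci = as.numeric(ci),
                 p_omnibus = as.numeric(p_omnibus),
                 p_bh = NA_real_),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result: %s ~ %s (+ %s), n = %d (%d outliers removed)>\n",
              x$dependent, paste(x$step1, collapse = " + "), x$step2,
              x$n, length(x$outliers_removed)))
  cat(sprintf("  delta adj R2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$delta_adj_r2, x$df[1], x$df[2], x$F_change, x$p_change))
  cat(sprintf("  beta (std) = %.3f [%.3f, %.3f], omnibus p = %.4g, BH p = %.4g\n",
              x$beta_focal, x$ci[1], x$ci[2], x$p_omnibus, x$p_bh))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p values p_(i) * m / i with monotonicity enforcement,
#' capped at 1, returned in input order. `m` may exceed the number of p
#' values (the study corrects over the number of planned models, 8, rather
#' than the number of tests passed in).
#'
#' @param p_values numeric vector of raw p values in [0, 1].
#' @param m number of comparisons (default `length(p_values)`).
#' @return adjusted p values, same order as the input.
#' @export
bh_correct <- function(p_values, m = length(p_values)) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p_values)")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
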