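# Small assay statistics: exponential doubling times from growth readouts,
# four-parameter log-logistic dose-response (IC50) fitting, and Welch t
# group testing with BH adjustment.

#' Exponential doubling time
#'
#' `t * ln(2) / ln(Nt / N0)` for a culture growing from readout `N0` to
#' `Nt` over time `t`. Scale-invariant in the readout (absorbances are as
#' good as cell counts).
#'
#' @param N0 Readout at seeding density (> 0).
#' @param Nt Readout at saturation density (> N0).
#' @param t Elapsed time (hours).
#' @return Doubling time in the units of `t`.
#' @examples
#' doubling_time(1, 4, 48)  # 24
#' @export
doubling_time <- function(N0, Nt, t) {
  if (any(N0 <= 0)) stop("N0 must be positive", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive", call. = FALSE)
  if (any(Nt <= N0)) {
    stop("no growth: Nt must exceed N0", call. = FALSE)
  }
  t * log(2) / log(Nt / N0)
}

#' Validated dose-response curve
#'
#' @param dose Concentrations (molar or any consistent unit), non-negative;
#'   a zero-dose control anchors the untreated asymptote and is excluded
#'   from the log-dose axis during fitting. At least 4 distinct
#'   concentrations are required for a four-parameter fit.
#' @param response Non-negative viabilities, replicate-resolved (one row per
#'   well).
#' @return Data frame of class `dose_response_curve`.
#' @export
dose_response_curve <- function(dose, response) {
  if (length(dose) != length(response)) {
    stop("dose and response lengths differ", call. = FALSE)
  }
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (any(response < 0)) stop("responses must be non-negative", call. = FALSE)
  if (length(unique(dose)) < 4L) {
    stop("need at least 4 distinct concentrations for a 4-parameter fit",
         call. = FALSE)
  }
  structure(data.frame(dose = dose, response = response),
            class = c("dose_response_curve", "data.frame"))
}

# f(x) = c + (d - c) / (1 + exp(b * (log x - loge))); x = 0 taken as the
# b-sign-appropriate limit (d for b > 0, c for b < 0)
ll4_weights <- function(x, b, loge) {
  w <- numeric(length(x))
  pos <- x > 0
  w[pos] <- 1 / (1 + exp(b * (log(x[pos]) - loge)))
  w[!pos] <- if (b > 0) 1 else 0
  w
}

ll4_predict <- function(x, b, c, d, loge) {
  w <- ll4_weights(x, b, loge)
  c + (d - c) * w
}

#' Fit a four-parameter log-logistic dose-response model
#'
#' Least-squares fit of `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))`
#' with lower asymptote `c`, upper asymptote `d`, hill slope `b` and
#' midpoint `e` (the IC50). The optimizer works on `(b, ln e)` with the
#' asymptotes profiled out linearly at each step (they enter the model
#' linearly given the weights), multistarted over a slope/midpoint grid, and
#' finishes with a joint Nelder-Mead refinement of all four parameters.
#' Zero-dose controls anchor the untreated asymptote and never enter the
#' log-dose axis. The `ll2_4` parametrization estimates `ln e` and reports
#' its standard error on the log scale; `ll4` reports the error of `e`
#' itself. Both give the same curve.
#'
#' @param curve A [dose_response_curve()] (or data frame with `dose`,
#'   `response`).
#' @param parametrization `"ll4"` or `"ll2_4"`.
#' @return Object of class `ll4_fit`: list with `coefficients` (b, c, d, e),
#'   `ic50`, `ic50_se`, `log_ic50`, `log_ic50_se`, `lower`, `upper`,
#'   `residual_ss`, `df_residual`, `sigma`, `vcov` (in the chosen
#'   parametrization), `converged`, `parametrization` and `fitted`.
#'   Non-convergence is an explicit failure state (`converged = FALSE`,
#'   `ic50 = NA`) carrying diagnostics, never silent garbage.
#' @export
fit_ll4 <- function(curve, parametrization = c("ll4", "ll2_4")) {
  parametrization <- match.arg(parametrization)
  if (!inherits(curve, "dose_response_curve")) {
    curve <- dose_response_curve(curve$dose, curve$response)
  }
  x <- curve$dose
  y <- curve$response
  if (stats::sd(y) == 0) stop("constant response; nothing to fit", call. = FALSE)

  profile_rss <- function(par) {
    b <- par[1]; loge <- par[2]
    if (!is.finite(b) || !is.finite(loge) || abs(b) > 50) return(Inf)
    w <- ll4_weights(x, b, loge)
    X <- cbind(1 - w, w)
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(Inf)
    sum(fit$residuals^2)
  }
  profile_cd <- function(par) {
    w <- ll4_weights(x, par[1], par[2])
    cf <- stats::lm.fit(cbind(1 - w, w), y)$coefficients
    c(c = unname(cf[1]), d = unname(cf[2]))
  }

  logx <- log(x[x > 0])
  loge_grid <- stats::quantile(logx, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  b_grid <- c(-4, -2, -1, -0.5, 0.5, 1, 2, 4)
  starts <- expand.grid(b = b_grid, loge = loge_grid)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), profile_rss,
                   method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) {
      best <- o
    }
  }
  fail <- function(msg) {
    structure(list(coefficients = c(b = NA, c = NA, d = NA, e = NA),
                   ic50 = NA_real_, ic50_se = NA_real_,
                   log_ic50 = NA_real_, log_ic50_se = NA_real_,
                   lower = NA_real_, upper = NA_real_,
                   residual_ss = NA_real_, df_residual = NA_integer_,
                   sigma = NA_real_, vcov = NULL, converged = FALSE,
                   parametrization = parametrization, fitted = NULL,
                   message = msg),
              class = "ll4_fit")
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(fail("no profiled start converged"))
  }

  cd <- profile_cd(best$par)
  full_rss <- function(par) {
    f <- ll4_predict(x, par[1], par[2], par[3], par[4])
    s <- sum((y - f)^2)
    if (!is.finite(s)) Inf else s
  }
  refine <- tryCatch(
    stats::optim(c(best$par[1], cd["c"], cd["d"], best$par[2]), full_rss,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(refine) || !is.finite(refine$value)) {
    return(fail("joint refinement failed"))
  }
  par <- refine$par
  b <- par[1]; cc <- par[2]; d <- par[3]; loge <- par[4]
  e <- exp(loge)
  rss <- refine$value
  dfres <- length(y) - 4L
  sigma <- if (dfres > 0) sqrt(rss / dfres) else NA_real_
  fitted <- ll4_predict(x, b, cc, d, loge)

  # parameter covariance from the Jacobian of fitted values at the optimum.
  # Always differentiated on the well-scaled (b, c, d, ln e) coordinates;
  # the ll4 parametrization's e-scale covariance follows by delta method
  # (d e / d ln e = e), avoiding a numerically singular crossproduct when
  # the IC50 sits at nanomolar magnitudes.
  theta <- c(b, cc, d, loge)
  J <- matrix(NA_real_, nrow = length(y), ncol = 4L)
  for (j in 1:4) {
    h <- max(1e-6, abs(theta[j]) * 1e-6)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (ll4_predict(x, up[1], up[2], up[3], up[4]) -
                 ll4_predict(x, dn[1], dn[2], dn[3], dn[4])) / (2 * h)
  }
  vcov_int <- tryCatch(sigma^2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(vcov_int)) {
    log_ic50_se <- sqrt(max(vcov_int[4, 4], 0))
    ic50_se <- log_ic50_se * e
    vcov <- if (parametrization == "ll4") {
      Tm <- diag(c(1, 1, 1, e))
      Tm %*% vcov_int %*% Tm
    } else vcov_int
    dimnames(vcov) <- list(c("b", "c", "d", "e"), c("b", "c", "d", "e"))
  } else {
    log_ic50_se <- NA_real_
    ic50_se <- NA_real_
    vcov <- NULL
  }

  structure(
    list(coefficients = c(b = b, c = cc, d = d, e = e),
         ic50 = e, ic50_se = ic50_se,
         log_ic50 = loge, log_ic50_se = log_ic50_se,
         lower = min(cc, d), upper = max(cc, d),
         residual_ss = rss, df_residual = dfres, sigma = sigma,
         vcov = vcov, converged = refine$convergence == 0,
         parametrization = parametrization, fitted = fitted,
         message = "ok"),
    class = "ll4_fit")
}

#' @export
print.ll4_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<ll4_fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat("<ll4_fit> (", x$parametrization, ") IC50 = ",
      format(x$ic50, digits = 4), " (SE ", format(x$ic50_se, digits = 3),
      "), slope b = ", format(x$coefficients["b"], digits = 3),
      ", asymptotes [", format(x$lower, digits = 3), ", ",
      format(x$upper, digits = 3), "], RSS = ",
      format(x$residual_ss, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Welch two-sample t test (unequal variances)
#'
#' @param a,b Numeric vectors, at least two observations each.
#' @return List with `t`, `df` (Welch-Satterthwaite), `p` (two-sided),
#'   `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    stop("both groups have zero variance; Welch t undefined", call. = FALSE)
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Compare two groups of IC50 estimates
#'
#' Welch two-sample t test on independent IC50 estimates (one per
#' experiment) from two cell lines / conditions.
#'
#' @param ic50_a,ic50_b Numeric vectors of IC50 estimates (>= 2 each).
#' @return A [welch_t()] result.
#' @export
compare_ic50 <- function(ic50_a, ic50_b) {
  welch_t(ic50_a, ic50_b)
}

#' Welch t tests across a comparison family with BH adjustment
#'
#' Runs [welch_t()] for every comparison and adjusts the p-values by
#' Benjamini-Hochberg across the family. Degenerate comparisons (both arms
#' with zero variance) are flagged and excluded from the BH family with a
#' warning; their p and q are `NA`.
#'
#' @param comparisons Named list; each element a list with numeric vectors
#'   `a` and `b`.
#' @return Data frame with one row per comparison: `comparison, t, df, p,
#'   q, flagged`. Order of rows follows the input; q-values are invariant
#'   to input order.
#' @export
group_test_bh <- function(comparisons) {
  if (length(comparisons) == 0L) stop("no comparisons", call. = FALSE)
  nm <- names(comparisons)
  if (is.null(nm)) nm <- paste0("comparison", seq_along(comparisons))
  rows <- lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    degenerate <- stats::var(cmp$a) == 0 && stats::var(cmp$b) == 0
    if (degenerate) {
      data.frame(comparison = nm[i], t = NA_real_, df = NA_real_,
                 p = NA_real_, flagged = TRUE, stringsAsFactors = FALSE)
    } else {
      w <- welch_t(cmp$a, cmp$b)
      data.frame(comparison = nm[i], t = w$t, df = w$df, p = w$p,
                 flagged = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(out$flagged)) {
    warning(sum(out$flagged),
            " degenerate comparison(s) excluded from the BH family")
  }
  out$q <- adjust_bh(out$p)
  out[, c("comparison", "t", "df", "p", "q", "flagged")]
}

#' Read a long-format assay table
#'
#' Long TSV with one measurement per row, e.g. `(sample, dose, replicate,
#' response)` for dose-response assays or `(sample, time, replicate,
#' absorbance)` for growth curves.
#'
#' @param path TSV path.
#' @param required Column names that must be present.
#' @return Data frame.
#' @export
read_assay_table <- function(path, required = c("sample", "dose",
                                                "replicate", "response")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("assay table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
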