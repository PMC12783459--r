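#' Coefficient of variation
#'
#' `cv = sd / mean`: the standard deviation expressed as a fraction of
#' the mean, the package's headline index of a measure's capacity to
#' spread individuals out. For instruments whose scale minimum is not
#' zero the plain ratio understates relative spread, so the adjusted
#' variant divides by the mean's distance above the scale minimum
#' instead: `adjusted cv = sd / (mean - scale_min)`.
#'
#' @param sd standard deviation.
#' @param mean sample mean.
#' @param scale_min lowest attainable score of the instrument; 0 gives
#'   the plain coefficient of variation.
#' @return the (adjusted) coefficient of variation.
#' @export
coef_variation <- function(sd, mean, scale_min = 0) {
  if (mean <= scale_min) {
    stop("coefficient of variation undefined: mean (", mean,
         ") must exceed scale_min (", scale_min, ")")
  }
  sd / (mean - scale_min)
}

#' Distributional summary of one variable
#'
#' The descriptive battery used to judge whether a measure can detect
#' individual differences: location and spread, quartiles, shape
#' (bias-corrected sample skewness G1 and excess kurtosis G2, the
#' formulas mainstream statistics GUIs print), the coefficient of
#' variation, the adjusted coefficient of variation when a scale
#' minimum is supplied, and a Shapiro-Wilk normality check (delegated
#' to [stats::shapiro.test()]). Quartiles use the default linear
#' interpolation convention (type 7).
#'
#' @param values numeric vector, at least 3 finite values.
#' @param scale_min optional lowest attainable score; enables
#'   `adjusted_cv`.
#' @return A `descriptives` list: n, mean, sd, q25, median, q75,
#'   skewness, excess_kurtosis, cv, adjusted_cv, shapiro_w, shapiro_p.
#'   Shape statistics are `NA` for constant samples, and `cv` is 0 there.
#' @export
describe <- function(values, scale_min = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || any(!is.finite(values))) {
    stop("describe() needs at least 3 finite values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (s > 0) {
    d <- values - m
    m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
    kurt <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
    sw <- stats::shapiro.test(values)
    shapiro_w <- unname(sw$statistic); shapiro_p <- sw$p.value
  } else {
    skew <- kurt <- NA_real_
    shapiro_w <- shapiro_p <- NA_real_
  }
  cv <- if (s == 0) 0 else if (m > 0) coef_variation(s, m) else NA_real_
  adj <- if (is.null(scale_min)) NA_real_ else coef_variation(s, m, scale_min)
  structure(
    list(n = n, mean = m, sd = s, q25 = q[1L], median = q[2L], q75 = q[3L],
         skewness = skew, excess_kurtosis = kurt,
         cv = cv, adjusted_cv = adj,
         shapiro_w = shapiro_w, shapiro_p = shapiro_p),
    class = "descriptives"
  )
}

#' @export
print.descriptives <- function(x, ...) {
  cat(sprintf("n=%d mean=%.3f sd=%.3f [%.3f, %.3f, %.3f]\n",
              x$n, x$mean, x$sd, x$q25, x$median, x$q75))
  cat(sprintf("skew=%.3f exkurt=%.3f cv=%.3f adj_cv=%s W=%.3f p=%.3f\n",
              x$skewness, x$excess_kurtosis, x$cv,
              ifelse(is.na(x$adjusted_cv), "-", sprintf("%.3f", x$adjusted_cv)),
              x$shapiro_w, x$shapiro_p))
  invisible(x)
}

#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations over the numeric columns of a
#' participant table, with two-sided p-values from the t distribution
#' and per-pair complete-case counts.
#'
#' @param data data.frame of participant records.
#' @param variables character vector of column names (default: all
#'   numeric columns).
#' @return A `correlation_table`: list of square matrices `r`, `p`, `n`.
#' @export
correlation_table <- function(data, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1L))]
  }
  k <- length(variables)
  if (k < 2L) stop("need at least two variables")
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- data[[variables[i]]]; y <- data[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      n[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (n[i, j] < 4L) {
        stop("fewer than 4 complete cases for ", variables[i], " vs ", variables[j])
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                            alternative = "two.sided")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  cat("Pearson r (pairwise complete):\n")
  print(round(x$r, digits))
  invisible(x)
}
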