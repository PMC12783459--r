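#' Fisher z transform of a correlation
#'
#' `fisher_z(r) = atanh(r)` stabilizes the variance of a Pearson
#' correlation for meta-analysis; its standard error depends only on
#' the sample size, `se_fisher(n) = 1 / sqrt(n - 3)`. `inv_fisher_z()`
#' maps back to the correlation scale.
#'
#' @param r correlation(s) with |r| < 1.
#' @param z Fisher-z value(s).
#' @param n per-study sample size(s), n >= 4.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' @rdname fisher_z
#' @export
se_fisher <- function(n) {
  if (any(n < 4)) stop("n must be >= 4")
  1 / sqrt(n - 3)
}

#' Per-study effect size
#'
#' One study's contribution to a pooled analysis: either a raw mean
#' with its standard error (`kind = "mean"`) or a correlation on the
#' Fisher-z scale (`kind = "fisher_z"`). For correlations you may give
#' either the z-scale `estimate` and `se` directly, or the raw
#' correlation `r` with sample size `n`, from which `estimate = atanh(r)`
#' and `se = 1/sqrt(n - 3)` are derived.
#'
#' @param study_id label.
#' @param kind `"mean"` or `"fisher_z"`.
#' @param estimate effect estimate on the pooling scale.
#' @param se standard error (> 0).
#' @param r raw correlation (alternative input for `kind = "fisher_z"`).
#' @param n sample size (used to derive `se` when absent).
#' @return An `effect_size` list.
#' @export
effect_size <- function(study_id, kind = c("mean", "fisher_z"),
                        estimate = NULL, se = NULL, r = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (kind == "fisher_z" && is.null(estimate)) {
    if (is.null(r)) stop("fisher_z effect needs `estimate` or `r`")
    estimate <- fisher_z(r)
  }
  if (is.null(se)) {
    if (kind != "fisher_z" || is.null(n)) {
      stop("`se` required (or `n` for kind = 'fisher_z')")
    }
    se <- se_fisher(n)
  }
  if (!is.finite(se) || se <= 0) stop("se must be > 0")
  structure(list(study_id = study_id, kind = kind,
                 estimate = estimate, se = se, n = n),
            class = "effect_size")
}

#' Pool effect sizes across studies
#'
#' Inverse-variance pooling of same-kind effects. `pool_fixed()` is the
#' fixed-effect model: weights `1/se^2`, pooled estimate the weighted
#' mean, pooled `se = 1/sqrt(sum(w))`. `pool_effects()` additionally
#' offers the DerSimonian-Laird random-effects model
#' (`method = "dl"`), which inflates the weights' denominators by the
#' moment estimate of the between-study variance tau^2 (truncated at 0,
#' where it reduces exactly to the fixed-effect answer). Confidence
#' intervals and the two-sided p use the normal reference distribution.
#'
#' @param effects list of [effect_size()] objects (all the same kind).
#' @param method `"fixed"` or `"dl"`.
#' @param conf_level confidence level for the interval.
#' @return A `meta_result`: pooled_estimate, pooled_se, ci_low, ci_high,
#'   z_stat, p, tau2, method, k.
#' @export
pool_effects <- function(effects, method = c("fixed", "dl"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  if (length(effects) < 1L) stop("need at least one effect")
  kinds <- vapply(effects, function(e) e$kind, character(1L))
  if (length(unique(kinds)) != 1L) {
    stop("cannot pool mixed effect kinds: ", paste(unique(kinds), collapse = ", "))
  }
  est <- vapply(effects, function(e) e$estimate, numeric(1L))
  se <- vapply(effects, function(e) e$se, numeric(1L))
  w <- 1 / se^2
  fixed <- sum(w * est) / sum(w)
  tau2 <- 0
  if (method == "dl" && length(est) > 1L) {
    q <- sum(w * (est - fixed)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (length(est) - 1L)) / cc)
    w <- 1 / (se^2 + tau2)
  }
  pooled <- sum(w * est) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- pooled / pooled_se
  structure(
    list(pooled_estimate = pooled, pooled_se = pooled_se,
         ci_low = pooled - zcrit * pooled_se,
         ci_high = pooled + zcrit * pooled_se,
         z_stat = z, p = 2 * stats::pnorm(-abs(z)),
         tau2 = tau2, method = method, k = length(est),
         kind = kinds[1L]),
    class = "meta_result"
  )
}

#' @rdname pool_effects
#' @export
pool_fixed <- function(effects, conf_level = 0.95) {
  pool_effects(effects, method = "fixed", conf_level = conf_level)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect pooled %s: %.3f (SE %.3f), 95%% CI (%.3f, %.3f), z = %.2f, p = %.3g\n",
              ifelse(x$method == "dl", "random", "fixed"), x$kind,
              x$pooled_estimate, x$pooled_se, x$ci_low, x$ci_high,
              x$z_stat, x$p))
  invisible(x)
}

#' Pool a full table of per-study effects
#'
#' Takes a long data.frame of per-study effects — columns `study`,
#' `label`, `kind` (`"mean"`, `"fisher_z"`, or `"correlation"` for raw
#' r/n rows), `estimate`, `se`, `n` (se or n may be `NA` where the
#' other applies) — and pools each label across studies. Correlation
#' effects are pooled on the Fisher-z scale and reported there, with a
#' back-transformed `pooled_r` column for convenience.
#'
#' @param effects_df long per-study effect table (see Details).
#' @param method pooling model, `"fixed"` (default) or `"dl"`.
#' @return data.frame, one row per label: label, kind, k, pooled, se,
#'   ci_low, ci_high, z, p, pooled_r.
#' @export
meta_table <- function(effects_df, method = c("fixed", "dl")) {
  method <- match.arg(method)
  needed <- c("study", "label", "kind", "estimate")
  missing_cols <- setdiff(needed, names(effects_df))
  if (length(missing_cols) > 0L) {
    stop("effects table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"se" %in% names(effects_df)) effects_df$se <- NA_real_
  if (!"n" %in% names(effects_df)) effects_df$n <- NA_real_
  labels <- unique(effects_df$label)
  rows <- lapply(labels, function(lab) {
    sub <- effects_df[effects_df$label == lab, , drop = FALSE]
    effs <- lapply(seq_len(nrow(sub)), function(i) {
      kind <- sub$kind[i]
      if (kind == "correlation") {
        effect_size(sub$study[i], "fisher_z", r = sub$estimate[i],
                    se = if (is.na(sub$se[i])) NULL else sub$se[i],
                    n = if (is.na(sub$n[i])) NULL else sub$n[i])
      } else {
        effect_size(sub$study[i], kind, estimate = sub$estimate[i],
                    se = if (is.na(sub$se[i])) NULL else sub$se[i],
                    n = if (is.na(sub$n[i])) NULL else sub$n[i])
      }
    })
    res <- pool_effects(effs, method = method)
    data.frame(label = lab, kind = res$kind, k = res$k,
               pooled = res$pooled_estimate, se = res$pooled_se,
               ci_low = res$ci_low, ci_high = res$ci_high,
               z = res$z_stat, p = res$p,
               pooled_r = if (res$kind == "fisher_z")
                 inv_fisher_z(res$pooled_estimate) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled two-study effect-size table
#'
#' The per-study summary inputs from the two validation studies of the
#' VR arcade task (n = 60 and n = 76): the Tickets and DMX means with
#' their standard errors, and all fourteen reported correlation pairs
#' already on the Fisher-z scale with SEs `1/sqrt(n-3)`. These printed
#' summaries are the inputs the pooled analysis is recomputed from.
#'
#' @return long effect data.frame suitable for [meta_table()].
#' @export
dmx_example_studies <- function() {
  path <- system.file("extdata", "study_effects.csv", package = "dmxr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
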