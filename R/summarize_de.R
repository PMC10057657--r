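# Empirical-Bayes moderated differential expression for the three-cohort
# (N / T / F1) one-way layout, with the fold-change + p + overall-F-FDR
# filter cascade and one-step Tukey biweight signal summaries.

#' One-step Tukey biweight robust average
#'
#' Robust location summary used for log2 signal values: one step of the Tukey
#' biweight starting from the median. With `u_i = (x_i - median) /
#' (c * MAD + eps)`, weights are `(1 - u_i^2)^2` for `|u_i| < 1` and 0
#' otherwise, and the summary is the weighted mean. If every weight is zero
#' the median is returned.
#'
#' @param x numeric vector of log2 intensities (at least one finite value).
#' @param c tuning constant (default 5); larger values downweight less and
#'   the summary converges to the arithmetic mean as `c` grows.
#' @param eps small stabilizer added to `c * MAD` (default 1e-4) so constant
#'   vectors are handled.
#' @return scalar log2 summary, always within `[min(x), max(x)]`.
#' @examples
#' tukey_biweight(c(1, 1, 1, 10))  # outlier downweighted, well below mean
#' @export
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    stop("tukey_biweight: need at least one finite value", call. = FALSE)
  }
  m <- stats::median(x)
  s <- c * stats::mad(x, center = m, constant = 1) + eps
  u <- (x - m) / s
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(m)
  sum(w * x) / sum(w)
}

#' Signed linear fold change from a log2 difference
#'
#' Converts a log2 difference `d` to the signed linear convention used in
#' the DE tables: `2^d` for `d >= 0` and `-2^(-d)` for `d < 0`, so the image
#' is `(-Inf, -1] U [1, Inf)` and -2 means 2-fold down.
#'
#' @param log2_diff finite numeric vector of log2 differences.
#' @return signed linear fold changes, same length.
#' @examples
#' signed_fc(c(0, 1, -1, -0.8875))
#' @export
signed_fc <- function(log2_diff) {
  if (any(!is.finite(log2_diff))) {
    stop("signed_fc: input must be finite", call. = FALSE)
  }
  ifelse(log2_diff >= 0, 2^log2_diff, -(2^(-log2_diff)))
}

#' Log2 difference from a signed linear fold change
#'
#' Inverse of [signed_fc()]: `log2(fc)` for `fc >= 1`, `-log2(-fc)` for
#' `fc <= -1`.
#'
#' @param fc signed linear fold changes with `|fc| >= 1`.
#' @return log2 differences.
#' @export
log2_from_signed_fc <- function(fc) {
  if (any(!is.finite(fc)) || any(abs(fc) < 1)) {
    stop("log2_from_signed_fc: |fc| must be finite and >= 1", call. = FALSE)
  }
  sign(fc) * log2(abs(fc))
}

#' Fit the one-way group layout per feature
#'
#' Computes per-feature group means, the pooled within-group residual
#' variance and its degrees of freedom for the one-way layout over the
#' cohorts present in the matrix.
#'
#' @param em `expression_matrix` (see [expression_matrix()]); at least two
#'   groups, each with at least two samples.
#' @return list with `means` (features x groups matrix), `s2` (pooled
#'   residual variance per feature), `df` (scalar residual degrees of
#'   freedom, `n_samples - n_groups`), `n` (named group sizes) and
#'   `zero_variance` (logical per feature; these get a 1e-10 variance floor
#'   in downstream statistics).
#' @export
fit_groups <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  groups <- intersect(.groups, unique(em$group_of))
  if (length(groups) < 2) {
    stop("fit_groups: need at least two groups", call. = FALSE)
  }
  n <- vapply(groups, function(g) sum(em$group_of == g), integer(1))
  if (any(n < 2)) {
    stop(sprintf("fit_groups: group '%s' has fewer than 2 samples (variance undefined)",
                 groups[which(n < 2)[1]]), call. = FALSE)
  }
  v <- em$values
  means <- matrix(NA_real_, nrow = nrow(v), ncol = length(groups),
                  dimnames = list(rownames(v), groups))
  rss_parts <- means
  for (g in groups) {
    cols <- v[, em$group_of == g, drop = FALSE]
    means[, g] <- rowMeans(cols)
    rss_parts[, g] <- rowSums((cols - means[, g])^2)
  }
  rss <- rowSums(rss_parts)
  df <- sum(n) - length(groups)
  s2 <- rss / df
  list(means = means, s2 = s2, df = df, n = n,
       zero_variance = s2 <= 0)
}

#' Estimate the empirical-Bayes variance prior by moment matching
#'
#' Matches the first two moments of `log s_g^2` to the scaled inverse
#' chi-square model for residual variances: with
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = var(e_g) - trigamma(d_g/2)` (monotone
#' bisection on `d0 in (0, 1e8]`, relative tolerance 1e-8); a non-positive
#' right-hand side gives an infinite `d0`. The prior variance `s0^2` then
#' solves `mean(e_g) = log s0^2 - digamma(d0/2) + log(d0/2)` (for infinite
#' `d0`, `s0^2 = exp(mean(e_g))`).
#'
#' @param s2 vector of residual variances (zero or negative entries are
#'   excluded with a warning; at least 2 positive values required).
#' @param d_g residual degrees of freedom of each `s2` (scalar).
#' @return list of class `ebayes_prior` with `d0` (possibly `Inf`) and
#'   `s0_sq`.
#' @export
estimate_ebayes_prior <- function(s2, d_g) {
  stopifnot(length(d_g) == 1, d_g > 0)
  drop <- !is.finite(s2) | s2 <= 0
  if (any(drop)) {
    warning(sprintf("excluding %d zero/non-finite variance feature(s) from prior estimation",
                    sum(drop)), call. = FALSE)
    s2 <- s2[!drop]
  }
  if (length(s2) < 2) {
    stop("estimate_ebayes_prior: need at least 2 features with positive variance",
         call. = FALSE)
  }
  e <- log(s2) - digamma(d_g / 2) + log(d_g / 2)
  rhs <- max(stats::var(e) - trigamma(d_g / 2), 0)
  if (rhs <= 0 || rhs < trigamma(1e8 / 2)) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    # trigamma is strictly decreasing: bisection on d0/2.
    lo <- 1e-8; hi <- 5e7
    if (trigamma(lo) < rhs) {
      d0 <- 2 * lo
    } else {
      for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (trigamma(mid) > rhs) lo <- mid else hi <- mid
        if ((hi - lo) / hi < 1e-8) break
      }
      d0 <- 2 * (lo + hi) / 2
    }
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("ebayes_prior: d0 = %s, s0^2 = %g\n",
              if (is.infinite(x$d0)) "Inf" else format(x$d0), x$s0_sq))
  invisible(x)
}

# Posterior (shrunken) variance. d0 = 0 returns s2 unchanged; d0 = Inf
# returns s0_sq.
.squeeze_var <- function(s2, d_g, prior) {
  s2 <- pmax(s2, 1e-10)
  if (is.infinite(prior$d0)) {
    rep(max(prior$s0_sq, 1e-10), length(s2))
  } else {
    (prior$d0 * prior$s0_sq + d_g * s2) / (prior$d0 + d_g)
  }
}

#' Moderated t-statistic for a group contrast
#'
#' Shrinks the per-feature residual variance toward the prior,
#' `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and tests
#' `t = diff / (s~ sqrt(v_c))` against a t distribution with `d0 + d_g`
#' degrees of freedom (standard normal in the infinite-`d0` limit). With
#' `d0 = 0` this is the ordinary pooled-variance t-test.
#'
#' @param diff contrast estimate(s): mean log2 difference, numerator minus
#'   denominator group.
#' @param v_c unscaled contrast variance, e.g. `1/n_a + 1/n_b` (scalar > 0).
#' @param s2 residual variance per feature.
#' @param d_g residual degrees of freedom (scalar).
#' @param prior `ebayes_prior` from [estimate_ebayes_prior()].
#' @return list with vectors `t` and `p` (two-sided; floored at the smallest
#'   positive double so downstream FDR adjustment stays in (0, 1]).
#' @export
moderated_t <- function(diff, v_c, s2, d_g, prior) {
  stopifnot(length(v_c) == 1, v_c > 0, inherits(prior, "ebayes_prior"))
  s2_tilde <- .squeeze_var(s2, d_g, prior)
  if (any(s2_tilde <= 0)) {
    stop("moderated_t: posterior variance is zero", call. = FALSE)
  }
  t <- diff / sqrt(s2_tilde * v_c)
  df_total <- prior$d0 + d_g
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, p = pmax(p, .Machine$double.xmin))
}

#' Moderated F-statistic across all groups
#'
#' Overall test that any group mean differs: between-group mean square over
#' the shrunken residual variance, on `(n_groups - 1, d0 + d_g)` degrees of
#' freedom. With `d0 = 0` this is the classical one-way ANOVA F.
#'
#' @param em `expression_matrix`, or a fit from [fit_groups()].
#' @param prior `ebayes_prior`.
#' @return list with vectors `f` and `p` (upper tail, floored as in
#'   [moderated_t()]).
#' @export
moderated_f <- function(em, prior) {
  fit <- if (inherits(em, "expression_matrix")) fit_groups(em) else em
  stopifnot(is.list(fit), !is.null(fit$means), inherits(prior, "ebayes_prior"))
  n <- fit$n
  k <- length(n)
  grand <- as.vector(fit$means %*% n) / sum(n)
  ms_between <- rowSums(sweep((fit$means - grand)^2, 2, n, `*`)) / (k - 1)
  s2_tilde <- .squeeze_var(fit$s2, fit$df, prior)
  f <- ms_between / s2_tilde
  df2 <- prior$d0 + fit$df
  p <- if (is.infinite(df2)) stats::pchisq((k - 1) * f, df = k - 1,
                                           lower.tail = FALSE)
       else stats::pf(f, k - 1, df2, lower.tail = FALSE)
  list(f = f, p = pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} p_(j) * n / j`, capped at 1 and
#' mapped back to input order (delegated to `stats::p.adjust`).
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("benjamini_hochberg: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter cascade specification
#'
#' The DE cascade keeps features with `|fold_change| >= fc_min` (inclusive),
#' `p_value < p_max`, overall-F FDR `< f_fdr_max` (both strict) and a
#' feature id starting with `species_prefix` (case-sensitive).
#'
#' @param fc_min minimum absolute signed fold change (default 1.5).
#' @param p_max contrast p-value bound (default 0.05, strict).
#' @param f_fdr_max overall moderated-F BH-FDR bound (default 0.005, strict).
#' @param species_prefix feature-id prefix to keep (default `"hsa"`).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(fc_min = 1.5, p_max = 0.05, f_fdr_max = 0.005,
                        species_prefix = "hsa") {
  stopifnot(fc_min >= 1, p_max > 0, p_max < 1, f_fdr_max > 0, f_fdr_max < 1)
  structure(list(fc_min = fc_min, p_max = p_max, f_fdr_max = f_fdr_max,
                 species_prefix = species_prefix), class = "filter_spec")
}

#' Apply the DE filter cascade
#'
#' @param results contrast result data.frame with columns `feature_id`,
#'   `fold_change`, `p_value`, `f_fdr` (as produced by [run_de()]).
#' @param spec [filter_spec()].
#' @return the rows passing all four rules, sorted by `fold_change`
#'   descending.
#' @export
de_filter <- function(results, spec = filter_spec()) {
  stopifnot(is.data.frame(results), inherits(spec, "filter_spec"))
  keep <- abs(results$fold_change) >= spec$fc_min &
    results$p_value < spec$p_max &
    results$f_fdr < spec$f_fdr_max &
    startsWith(results$feature_id, spec$species_prefix)
  out <- results[keep, , drop = FALSE]
  out[order(-out$fold_change, out$feature_id), , drop = FALSE]
}

#' Run moderated differential expression for both contrasts
#'
#' Fits the one-way N/T/F1 layout per feature, estimates the
#' empirical-Bayes variance prior, and computes for each contrast (T vs N and
#' F1 vs T) the mean log2 difference, signed fold change, moderated t and
#' p-value, per-contrast BH FDR, and the shared overall moderated-F BH FDR
#' across the three groups. Per-group biweight signal summaries
#' ([tukey_biweight()]) are reported alongside the statistics.
#'
#' @param em `expression_matrix` with all three groups.
#' @param spec [filter_spec()] used to populate `passes_filter`.
#' @param prior optional `ebayes_prior`; estimated from the data when `NULL`.
#'   If no feature has positive residual variance the prior falls back to
#'   `d0 = Inf`, `s0^2 = 1e-10` with a warning (degenerate noiseless input).
#' @return list with `TvN` and `F1vT` contrast data.frames (columns
#'   `feature_id`, `avg_N`, `avg_T`, `avg_F1`, `log2_diff`, `fold_change`,
#'   `t_mod`, `p_value`, `fdr`, `f_fdr`, `passes_filter`, `zero_variance`),
#'   the `prior`, and the `fit`.
#' @export
run_de <- function(em, spec = filter_spec(), prior = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  missing_groups <- setdiff(.groups, unique(em$group_of))
  if (length(missing_groups) > 0) {
    stop(sprintf("run_de: group(s) %s absent from the matrix",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)
  }
  fit <- fit_groups(em)
  if (is.null(prior)) {
    pos <- fit$s2[fit$s2 > 0 & is.finite(fit$s2)]
    if (length(pos) >= 2) {
      prior <- suppressWarnings(estimate_ebayes_prior(fit$s2, fit$df))
    } else {
      warning("no positive residual variances; using a degenerate prior (d0 = Inf, s0^2 = 1e-10)",
              call. = FALSE)
      prior <- structure(list(d0 = Inf, s0_sq = 1e-10), class = "ebayes_prior")
    }
  }
  fstat <- moderated_f(fit, prior)
  f_fdr <- benjamini_hochberg(fstat$p)
  biweight <- vapply(.groups, function(g) {
    apply(em$values[, em$group_of == g, drop = FALSE], 1, tukey_biweight)
  }, numeric(nrow(em$values)))
  contrast <- function(num, den) {
    diff <- fit$means[, num] - fit$means[, den]
    v_c <- 1 / fit$n[[num]] + 1 / fit$n[[den]]
    tt <- moderated_t(diff, v_c, fit$s2, fit$df, prior)
    df <- data.frame(feature_id = rownames(em$values),
                     avg_N = biweight[, "N"], avg_T = biweight[, "T"],
                     avg_F1 = biweight[, "F1"],
                     log2_diff = diff, fold_change = signed_fc(diff),
                     t_mod = tt$t, p_value = tt$p,
                     fdr = benjamini_hochberg(tt$p), f_fdr = f_fdr,
                     zero_variance = fit$zero_variance,
                     stringsAsFactors = FALSE, row.names = NULL)
    df$passes_filter <- abs(df$fold_change) >= spec$fc_min &
      df$p_value < spec$p_max & df$f_fdr < spec$f_fdr_max &
      startsWith(df$feature_id, spec$species_prefix)
    df
  }
  list(TvN = contrast("T", "N"), F1vT = contrast("F1", "T"),
       prior = prior, fit = fit)
}
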