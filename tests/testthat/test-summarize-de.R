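# Statistical core: biweight summaries, signed fold changes, the one-way
# fit, the empirical-Bayes prior, moderated t/F, BH and the filter cascade.

test_that("tukey_biweight matches the one-step weight formula", {
  expect_equal(tukey_biweight(c(3, 3, 3)), 3)
  expect_equal(tukey_biweight(c(1, 2, 3)), 2)
  # brute-force evaluation of the stated formula as oracle
  x <- c(1, 1.2, 0.9, 1.1, 10)
  cc <- 5; eps <- 1e-4
  m <- median(x)
  s <- cc * median(abs(x - m)) + eps
  u <- (x - m) / s
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  expect_equal(tukey_biweight(x, c = cc, eps = eps), sum(w * x) / sum(w))
  # the outlier is fully downweighted when MAD collapses
  y <- c(1, 1, 1, 10)
  expect_equal(tukey_biweight(y), 1)
  expect_lt(tukey_biweight(y), mean(y))
  expect_error(tukey_biweight(numeric(0)), "finite")
})

test_that("tukey_biweight converges to the mean and stays in range", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), sd = sample(1:3, 1))
    bw <- tukey_biweight(x)
    expect_gte(bw, min(x))
    expect_lte(bw, max(x))
    expect_equal(tukey_biweight(x, c = 1e9), mean(x), tolerance = 1e-6)
  }
})

test_that("signed_fc follows the signed linear convention", {
  expect_equal(signed_fc(0), 1)
  expect_equal(signed_fc(c(1, -1)), c(2, -2))
  expect_equal(signed_fc(-0.8875), -1.85, tolerance = 0.005 / 1.85)
  set.seed(2)
  d <- runif(50, -5, 5)
  expect_equal(signed_fc(-d), -signed_fc(d))
  expect_true(all(abs(signed_fc(d)) >= 1))
  expect_equal(log2_from_signed_fc(signed_fc(d)), d)
})

test_that("fit_groups reproduces hand-computed pooled variances", {
  v <- rbind(f1 = c(0, 2, 1, 3, 2, 4))
  em <- expression_matrix(
    matrix(v, nrow = 1, dimnames = list("f1", paste0("s", 1:6))),
    setNames(c("N", "N", "T", "T", "F1", "F1"), paste0("s", 1:6)))
  fit <- fit_groups(em)
  expect_equal(unname(fit$means[1, ]), c(1, 2, 3))
  expect_equal(fit$df, 3)
  expect_equal(unname(fit$s2), 2)  # rss = 2+2+2 over df 3
  # two-group exact fit
  em2 <- expression_matrix(
    matrix(c(1, 1, 3, 3), nrow = 1,
           dimnames = list("f1", paste0("s", 1:4))),
    setNames(c("N", "N", "T", "T"), paste0("s", 1:4)))
  fit2 <- fit_groups(em2)
  expect_equal(unname(fit2$means[1, ]), c(1, 3))
  expect_equal(unname(fit2$s2), 0)
  expect_equal(fit2$df, 2)
  expect_true(fit2$zero_variance[1])
  # a singleton group is rejected
  em3 <- expression_matrix(
    matrix(1:3, nrow = 1, dimnames = list("f1", paste0("s", 1:3))),
    setNames(c("N", "N", "T"), paste0("s", 1:3)))
  expect_error(fit_groups(em3), "fewer than 2")
})

test_that("prior estimation recovers known hyperparameters and edge cases", {
  # identical variances: no excess dispersion, d0 infinite
  pr <- estimate_ebayes_prior(rep(0.3, 50), d_g = 3)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq,
               exp(log(0.3) - digamma(1.5) + log(1.5)))
  # simulation with known truth (scaled inverse chi-square variances)
  set.seed(11)
  n <- 200; d0 <- 4; s0 <- 0.05; dg <- 3
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, dg) / dg
  est <- estimate_ebayes_prior(s2, dg)
  expect_gt(est$d0, d0 * 0.5); expect_lt(est$d0, d0 * 1.5)
  expect_gt(est$s0_sq, s0 * 0.75); expect_lt(est$s0_sq, s0 * 1.25)
  expect_error(estimate_ebayes_prior(0.5, 3), "at least 2")
  expect_warning(estimate_ebayes_prior(c(0, 0.2, 0.3), 3), "excluding")
})

test_that("prior estimation agrees with the independent limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(23)
  sigma2 <- 6 * 0.1 / rchisq(300, 6)
  s2 <- sigma2 * rchisq(300, 4) / 4
  est <- estimate_ebayes_prior(s2, 4)
  sq <- limma::squeezeVar(s2, 4)
  expect_equal(est$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(est$s0_sq, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t matches hand evaluation and classical limits", {
  # hand fixture
  pr <- make_prior(4, 0.1)
  res <- moderated_t(1, 0.5, 0.2, 3, pr)
  s2_tilde <- (4 * 0.1 + 3 * 0.2) / 7
  expect_equal(res$t, 1 / sqrt(s2_tilde * 0.5))
  expect_equal(res$p, 2 * pt(-abs(res$t), df = 7))
  # null case
  null <- moderated_t(0, 0.5, 0.2, 3, pr)
  expect_equal(null$t, 0); expect_equal(null$p, 1)
  # d0 = 0 equals the ordinary pooled two-sample t
  set.seed(7)
  for (i in 1:25) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    res <- moderated_t(mean(a) - mean(b), 1 / na + 1 / nb, s2,
                       na + nb - 2, prior_d0_zero)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated F matches hand evaluation and classical ANOVA", {
  # hand fixture on the fit_groups example: means 1,2,3; n = 2 each; s2 = 2
  v <- matrix(c(0, 2, 1, 3, 2, 4), nrow = 1,
              dimnames = list("f1", paste0("s", 1:6)))
  em <- expression_matrix(v, setNames(c("N", "N", "T", "T", "F1", "F1"),
                                      paste0("s", 1:6)))
  pr <- make_prior(4, 0.1)
  res <- moderated_f(em, pr)
  s2_tilde <- (4 * 0.1 + 3 * 2) / 7
  ms_between <- (2 * (1 - 2)^2 + 2 * (2 - 2)^2 + 2 * (3 - 2)^2) / 2
  expect_equal(unname(res$f), ms_between / s2_tilde)
  expect_equal(unname(res$p),
               pf(ms_between / s2_tilde, 2, 7, lower.tail = FALSE))
  # equal group means: F = 0, p = 1
  v0 <- matrix(rep(c(1, 2), 3)[c(1, 2, 1, 2, 1, 2)], nrow = 1,
               dimnames = list("f1", paste0("s", 1:6)))
  em0 <- expression_matrix(v0, setNames(c("N", "N", "T", "T", "F1", "F1"),
                                        paste0("s", 1:6)))
  res0 <- moderated_f(em0, pr)
  expect_equal(unname(res0$f), 0); expect_equal(unname(res0$p), 1)
  # d0 = 0 equals classical one-way ANOVA
  set.seed(9)
  for (i in 1:25) {
    em_r <- toy_matrix(n_features = 1, sizes = c(N = 3, T = 4, F1 = 3),
                       noise_sd = 1, seed = i)
    res <- moderated_f(em_r, prior_d0_zero)
    y <- em_r$values[1, ]
    an <- anova(lm(y ~ factor(em_r$group_of)))
    expect_equal(unname(res$f), an$`F value`[1], tolerance = 1e-10)
    expect_equal(unname(res$p), an$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\(0, 1\\]")
  # all multisets of length <= 6 from a fixed grid (order invariance is
  # checked separately, so multisets cover all vectors)
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 1)
  for (len in 1:6) {
    sets <- utils::combn(length(grid) + len - 1, len)
    for (j in seq_len(ncol(sets))) {
      p <- grid[sets[, j] - seq_len(len) + 1]
      expect_equal(benjamini_hochberg(p), bh_oracle(p))
    }
  }
  # permutation invariance and monotonicity vs raw p
  set.seed(3)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  expect_true(all(benjamini_hochberg(p) >= p))
})

test_that("the DE filter cascade applies all four rules inclusively/strictly", {
  tab <- data.frame(
    feature_id = c("hsa-miR-a", "mmu-miR-b", "hsa-miR-c", "hsa-miR-d",
                   "hsa-miR-e", "hsa-miR-f"),
    fold_change = c(1.5, 2.0, 1.49, -3.0, 2.5, 2.5),
    p_value = c(0.04, 0.04, 0.01, 0.05, 0.01, 0.01),
    f_fdr = c(0.004, 0.004, 0.001, 0.001, 0.005, 0.0049),
    stringsAsFactors = FALSE)
  out <- de_filter(tab, filter_spec())
  # boundary |FC| = 1.5 kept; mmu dropped; p = 0.05 and f_fdr = 0.005 strict
  expect_identical(out$feature_id, c("hsa-miR-f", "hsa-miR-a"))
  # brute-force scan oracle on random tables
  set.seed(13)
  for (i in 1:10) {
    n <- 30
    tab <- data.frame(
      feature_id = paste0(sample(c("hsa", "mmu"), n, replace = TRUE),
                          "-miR-", seq_len(n)),
      fold_change = sample(c(-1, 1), n, TRUE) * runif(n, 1, 4),
      p_value = runif(n, 0, 0.1), f_fdr = runif(n, 0, 0.01),
      stringsAsFactors = FALSE)
    keep <- vapply(seq_len(n), function(r) {
      abs(tab$fold_change[r]) >= 1.5 && tab$p_value[r] < 0.05 &&
        tab$f_fdr[r] < 0.005 && startsWith(tab$feature_id[r], "hsa")
    }, logical(1))
    out <- de_filter(tab, filter_spec())
    expect_setequal(out$feature_id, tab$feature_id[keep])
    expect_false(is.unsorted(rev(out$fold_change)))
  }
})

test_that("moderated t p-values are uniform under the null", {
  em <- simulate_triomics(sim_config(n_mirna = 2000, de_fraction_tvn = 0,
                                     de_fraction_f1vt = 0,
                                     both_same_direction_count = 0,
                                     transcriptional_decoy_fraction = 0,
                                     decoy_target_count = 0,
                                     seed = 101))$expression
  de <- run_de(em)
  ks <- suppressWarnings(ks.test(de$TvN$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("run_de wires contrasts, FDR columns and the filter flag together", {
  shifts <- data.frame(feature = c(1, 2), comparison = c("TvN", "F1vT"),
                       delta = c(2, -2), stringsAsFactors = FALSE)
  em <- toy_matrix(n_features = 60, sizes = c(N = 5, T = 7, F1 = 8),
                   noise_sd = 0.2, shifts = shifts, seed = 21)
  de <- run_de(em)
  expect_identical(names(de$TvN)[1:6],
                   c("feature_id", "avg_N", "avg_T", "avg_F1", "log2_diff",
                     "fold_change"))
  expect_equal(de$TvN$fold_change, signed_fc(de$TvN$log2_diff))
  expect_identical(de$TvN$f_fdr, de$F1vT$f_fdr)
  expect_true(de$TvN$passes_filter[1])
  expect_true(de$F1vT$passes_filter[2])
  expect_false(de$F1vT$passes_filter[1])  # planted only in TvN
  # moderated t cross-check against limma on the same design and contrast
  skip_if_not_installed("limma")
  design <- stats::model.matrix(~ 0 + factor(em$group_of,
                                             levels = c("N", "T", "F1")))
  colnames(design) <- c("N", "T", "F1")
  fit <- limma::lmFit(em$values, design)
  fit <- limma::contrasts.fit(
    fit, limma::makeContrasts(TvN = T - N, levels = design))
  fit <- limma::eBayes(fit)
  lp <- limma::topTable(fit, coef = "TvN", number = Inf, sort.by = "none")
  expect_gt(cor(de$TvN$t_mod, fit$t[, "TvN"]), 0.9999)
  expect_equal(de$TvN$p_value, lp$P.Value, tolerance = 0.02)
})
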