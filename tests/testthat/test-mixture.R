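test_that("candidate model count is 2(ploidy+1) across ploidies", {
  expect_equal(nrow(mixture_models(3)), 8)
  expect_equal(nrow(mixture_models(2)), 6)
  expect_equal(nrow(mixture_models(1)), 4)
  for (p in 1:6) expect_equal(nrow(mixture_models(p)), 2 * (p + 1))
  expect_setequal(unique(mixture_models(3)$variance_mode), c("E", "V"))
  expect_error(mixture_models(0))
})

test_that("initial partition follows the allele-frequency heuristic", {
  # two clean homozygote blocks: empirical classes {BB, AA}, p = 0.5,
  # renormalized binomial masses are (1/2, 1/2) -> sizes (3, 3)
  ip <- initial_partition(c(-2, -2, -2, 2, 2, 2), ploidy = 2, g = 2,
                          reference_means = reference_means(2))
  expect_equal(ip$sizes, c(3L, 3L))
  expect_equal(ip$means, c(-2, 2))
  expect_equal(ip$p_hat, 0.5)

  # single cluster: everything in one block
  ip1 <- initial_partition(rep(0.16, 10), 2, 1, reference_means(2))
  expect_equal(ip1$sizes, 10L)
  expect_equal(ip1$means, 0.16)

  expect_error(initial_partition(rnorm(5), 3, 6, c(-2, -1, 1, 2)),
               "insufficient")
})

test_that("initial partition seeds every cluster and preserves order", {
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(1, 0.05, 0.95)
    x <- reference_means(3)[rbinom(60, 3, p) + 1] + rnorm(60, 0, 0.2)
    for (g in 1:4) {
      ip <- initial_partition(x, 3, g, reference_means(3))
      expect_equal(sum(ip$sizes), 60)
      expect_true(all(ip$sizes >= 1))
      expect_true(!is.unsorted(ip$means))
    }
  }
})

test_that("single-Gaussian fit recovers the sample moments", {
  set.seed(5)
  x <- rnorm(400, 0, 1)
  fit <- fit_contrast_mixture(x, 1, "E", ploidy = 2,
                              reference_means = reference_means(2))
  expect_true(fit$converged)
  expect_lt(abs(fit$means - mean(x)), 3 * sd(x) / sqrt(400))
  expect_lt(abs(fit$variances - var(x)) / var(x), 0.10)
})

test_that("well-separated two-cluster mixtures are recovered in both modes", {
  set.seed(6)
  x <- c(rnorm(200, -2, 0.05), rnorm(200, 2, 0.05))
  for (mode in c("E", "V")) {
    fit <- fit_contrast_mixture(x, 2, mode, ploidy = 2,
                                reference_means = reference_means(2))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$means - c(-2, 2))), 0.05)
    expect_lt(max(abs(fit$weights - 0.5)), 0.05)
  }
})

test_that("identical observations hit the variance floor and still converge", {
  ctrl <- em_control()
  fit <- fit_contrast_mixture(rep(0.4, 50), 1, "E", ploidy = 2,
                              reference_means = reference_means(2),
                              control = ctrl)
  expect_true(fit$converged)
  expect_equal(unname(fit$variances), ctrl$variance_floor)
})

test_that("reported loglik matches a brute-force evaluation to 1e-10", {
  set.seed(8)
  for (g in 1:3) {
    x <- rnorm(12)
    fit <- fit_contrast_mixture(x, g, "V", ploidy = 2,
                                reference_means = reference_means(2))
    if (!fit$converged) next
    expect_equal(fit$loglik,
                 oracle_loglik(x, fit$weights, fit$means, fit$variances),
                 tolerance = 1e-10)
  }
})

test_that("the penalized EM objective is non-decreasing over iterations", {
  set.seed(9)
  x <- c(rnorm(60, -1, 0.4), rnorm(40, 1, 0.7))
  for (mode in c("E", "V")) {
    fit <- fit_contrast_mixture(x, 2, mode, ploidy = 2,
                                reference_means = reference_means(2),
                                keep_trace = TRUE)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("fits are label-sorted and invariant to input permutation", {
  set.seed(10)
  x <- c(rnorm(50, -1.8, 0.1), rnorm(70, 0.2, 0.1), rnorm(30, 1.9, 0.1))
  f1 <- fit_contrast_mixture(x, 3, "V", ploidy = 2,
                             reference_means = reference_means(2))
  f2 <- fit_contrast_mixture(sample(x), 3, "V", ploidy = 2,
                             reference_means = reference_means(2))
  expect_true(!is.unsorted(f1$means))
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("responsibility rows sum to one and ICL <= BIC always", {
  set.seed(12)
  x <- c(rnorm(80, -0.5, 0.5), rnorm(80, 0.6, 0.5))  # overlapping on purpose
  for (g in 1:3) {
    fit <- fit_contrast_mixture(x, g, "E", ploidy = 2,
                                reference_means = reference_means(2))
    if (!fit$converged) next
    expect_equal(rowSums(fit$responsibilities), rep(1, fit$n), tolerance = 1e-9)
    expect_lte(fit$icl, fit$bic)
    expect_equal(fit$n_params, 2 * g)
  }
  fv <- fit_contrast_mixture(x, 2, "V", ploidy = 2,
                             reference_means = reference_means(2))
  expect_equal(fv$n_params, 3 * 2 - 1)
})

test_that("ICL equals BIC under hard classification, and g=1 scores in closed form", {
  set.seed(13)
  x <- c(rnorm(100, -3, 0.01), rnorm(100, 3, 0.01))
  fit <- fit_contrast_mixture(x, 2, "E", ploidy = 2,
                              reference_means = reference_means(2))
  expect_equal(fit$icl, fit$bic, tolerance = 1e-6)  # entropy ~ 0

  x1 <- rnorm(50)
  f1 <- fit_contrast_mixture(x1, 1, "E", ploidy = 2,
                             reference_means = reference_means(2))
  expect_equal(f1$entropy, 0)
  expect_equal(f1$icl, 2 * f1$loglik - 2 * log(50))
})

test_that("ICL at fixed parameters matches a hand computation", {
  # 3 points, pi = (.5, .5), mu = (-1, 1), var = (1, 1)
  x <- c(-1, 0, 1)
  post <- mixture_posterior(x, c(0.5, 0.5), c(-1, 1), c(1, 1))
  # hand-computed pieces
  d1 <- 0.5 * dnorm(x, -1, 1); d2 <- 0.5 * dnorm(x, 1, 1)
  ll <- sum(log(d1 + d2))
  z <- cbind(d1, d2) / (d1 + d2)
  ent <- -sum(z * log(z))
  n_params <- 3 * 2 - 1
  bic <- 2 * ll - n_params * log(3)
  expect_equal(post$loglik, ll, tolerance = 1e-12)
  fake <- structure(list(loglik = post$loglik, n = 3, n_params = n_params,
                         responsibilities = post$responsibilities,
                         converged = TRUE), class = "mixfit")
  scored <- score_fit(fake)
  expect_equal(scored$bic, bic, tolerance = 1e-12)
  expect_equal(scored$icl, bic - 2 * ent, tolerance = 1e-12)
})

test_that("loglik agrees with mclust on the same data and parameter count on E/V", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(14)
  x <- c(rnorm(150, -1.8, 0.12), rnorm(150, 0.2, 0.12), rnorm(100, 1.9, 0.12))
  fit <- fit_contrast_mixture(x, 3, "V", ploidy = 2,
                              reference_means = reference_means(2))
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  # same data, same model family: the two optima should essentially agree
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("tidy() and glance() expose the fit as tibbles", {
  set.seed(15)
  fit <- fit_contrast_mixture(rnorm(60), 2, "E", ploidy = 2,
                              reference_means = reference_means(2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$size), 60, tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("loglik", "bic", "icl", "converged") %in% names(gl)))
})
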