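#' Candidate mixture models for a given ploidy
#'
#' A marker on an array can show between one and `ploidy + 1` genotype
#' clusters in the contrast dimension, and each cluster count is fit under two
#' variance structures: `"E"` (all clusters share one variance) and `"V"`
#' (cluster-specific variances). A triploid marker therefore has 4 x 2 = 8
#' candidate models, a diploid one 3 x 2 = 6.
#'
#' @param ploidy Integer ploidy >= 1.
#' @return Tibble with columns `g` (cluster count) and `variance_mode`.
#' @export
mixture_models <- function(ploidy) {
  if (length(ploidy) != 1 || is.na(ploidy) || ploidy < 1 || ploidy != round(ploidy)) {
    stop("ploidy must be a single integer >= 1")
  }
  tidyr::expand_grid(g = seq_len(ploidy + 1), variance_mode = c("E", "V"))
}

#' EM settings for the mixture engine
#'
#' @param tol Relative log-posterior change below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param variance_floor Lower bound on cluster variances (contrast units
#'   squared); prevents degenerate zero-variance spikes.
#' @param kappa Strength of the conjugate normal prior on each cluster mean,
#'   in pseudo-observations; the prior is centred on the initial left-to-right
#'   block means and anchors EM to that ordering without biasing
#'   well-populated clusters.
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol = 1e-6, max_iter = 500L, variance_floor = 1e-4,
                       kappa = 1.0) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 variance_floor = variance_floor, kappa = kappa),
            class = "em_control")
}

#' Allele-frequency-informed initial partition
#'
#' Seeds EM the way the calling method prescribes: each observation is
#' hard-assigned to the nearest reference contrast mean, giving a rough allele
#' frequency `p = mean(dosage) / ploidy` (clipped to `[1/(2n), 1 - 1/(2n)]`).
#' The `g` dosage classes to seed are ranked by their empirical assignment
#' counts (ties broken by binomial mass, then by lower dosage), their
#' `Binomial(ploidy, p)` masses are renormalized into expected proportions,
#' and cluster sizes `n_1..n_g` follow by largest-remainder rounding with a
#' minimum of one observation per cluster. Sorting the contrasts and cutting
#' them into consecutive blocks of those sizes yields the initial block means.
#'
#' @param contrasts Numeric vector of contrasts (`NA` allowed, dropped).
#' @param ploidy Ploidy (2 or 3 in practice).
#' @param g Number of clusters to seed, `1 <= g <= ploidy + 1`.
#' @param reference_means Ascending vector of `ploidy + 1` reference contrast
#'   means (see [reference_means()]).
#' @return List of class `init_partition` with `sizes` (length `g`, sums to
#'   the number of non-missing contrasts) and `means` (block means,
#'   ascending).
#' @export
initial_partition <- function(contrasts, ploidy, g, reference_means) {
  x <- contrasts[is.finite(contrasts)]
  n <- length(x)
  if (n < g) stop("insufficient observations: ", n, " contrasts for g = ", g)
  stopifnot(length(reference_means) == ploidy + 1, g >= 1, g <= ploidy + 1)
  dos <- apply(abs(outer(x, reference_means, "-")), 1, which.min) - 1L
  p_hat <- mean(dos) / ploidy
  p_hat <- min(max(p_hat, 1 / (2 * n)), 1 - 1 / (2 * n))
  mass <- stats::dbinom(0:ploidy, ploidy, p_hat)
  emp <- tabulate(dos + 1L, nbins = ploidy + 1)
  ord <- order(-emp, -mass, 0:ploidy)
  classes <- sort(ord[seq_len(g)])            # dosage order preserved
  w <- mass[classes] / sum(mass[classes])
  sizes <- largest_remainder(w, n)
  cuts <- cumsum(c(0L, sizes))
  xs <- sort(x)
  means <- vapply(seq_len(g), function(k) mean(xs[(cuts[k] + 1):cuts[k + 1]]),
                  numeric(1))
  structure(list(sizes = sizes, means = means, classes = classes - 1L,
                 p_hat = p_hat), class = "init_partition")
}

# Largest-remainder apportionment of n among proportions w, each share >= 1.
largest_remainder <- function(w, n) {
  g <- length(w)
  stopifnot(n >= g)
  base <- floor(w * n)
  rem <- w * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  while (any(base == 0)) {
    i <- which(base == 0)[1]
    j <- which.max(base)
    base[i] <- 1
    base[j] <- base[j] - 1
  }
  as.integer(base)
}

#' Fit a univariate normal mixture to contrasts by MAP-EM
#'
#' Fits `g` Gaussian clusters to the non-missing contrasts under the `"E"`
#' (equal variance) or `"V"` (cluster-specific variance) structure. Cluster
#' means carry a conjugate normal prior centred on the initial block means
#' (strength `control$kappa` pseudo-observations), so the M-step is a MAP
#' update and the penalized objective (log-likelihood plus log prior) is
#' non-decreasing over iterations. The reported `loglik` is the observed-data
#' mixture log-likelihood with the prior excluded; `bic` and `icl` are on the
#' larger-is-better scale (see [score_fit()]).
#'
#' A fit where a cluster loses essentially all mass despite the variance
#' floor is flagged `converged = FALSE` and is skipped by model selection.
#'
#' @param contrasts Numeric vector (`NA` dropped).
#' @param g Cluster count.
#' @param variance_mode `"E"` or `"V"`.
#' @param init `init_partition` object; computed from `reference_means` via
#'   [initial_partition()] when omitted.
#' @param control An [em_control()] list.
#' @param ploidy,reference_means Used only to build `init` when it is missing.
#' @param keep_trace Record the penalized objective per iteration (for
#'   diagnostics).
#' @return Object of class `mixfit`: cluster count `g`, `variance_mode`,
#'   `weights`, `means` (ascending), `variances`, `loglik`, `bic`, `icl`,
#'   `entropy`, `n`, `n_params`, `responsibilities` (n x g), `converged`,
#'   `iterations`.
#' @export
fit_contrast_mixture <- function(contrasts, g, variance_mode = c("E", "V"),
                                 init = NULL, control = em_control(),
                                 ploidy = NULL, reference_means = NULL,
                                 keep_trace = FALSE) {
  variance_mode <- match.arg(variance_mode)
  x <- contrasts[is.finite(contrasts)]
  n <- length(x)
  if (n < g) stop("insufficient observations: ", n, " contrasts for g = ", g)
  if (is.null(init)) {
    if (is.null(ploidy) || is.null(reference_means)) {
      stop("supply either `init` or both `ploidy` and `reference_means`")
    }
    init <- initial_partition(x, ploidy, g, reference_means)
  }
  kappa <- control$kappa
  floor_v <- control$variance_floor
  m0 <- init$means

  # initial hard partition of the sorted contrasts
  ord <- order(x)
  z <- matrix(0, n, g)
  cuts <- cumsum(c(0L, init$sizes))
  for (k in seq_len(g)) z[ord[(cuts[k] + 1):cuts[k + 1]], k] <- 1

  mu <- m0
  sig2 <- rep(max(stats::var(x), floor_v), g)
  if (is.na(sig2[1])) sig2 <- rep(floor_v, g)
  w <- init$sizes / n
  obj_old <- -Inf
  trace <- if (keep_trace) numeric(0) else NULL
  converged <- FALSE
  collapsed <- FALSE
  it <- 0L

  m_step <- function(z) {
    nk <- colSums(z)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- (colSums(z * x) + kappa * m0) / (nk + kappa)
    ss <- colSums(z * outer(x, mu, "-")^2) + kappa * (mu - m0)^2
    if (variance_mode == "E") {
      sig2 <- rep(max(sum(ss) / (n + g), floor_v), g)
    } else {
      sig2 <- pmax(ss / (nk + 1), floor_v)
    }
    list(w = w, mu = mu, sig2 = sig2)
  }

  dens <- function(w, mu, sig2) {
    d <- vapply(seq_len(g), function(k) w[k] * stats::dnorm(x, mu[k], sqrt(sig2[k])),
                numeric(n))
    matrix(d, n, g)
  }
  log_prior <- function(mu, sig2) {
    sum(0.5 * log(kappa / (2 * pi * sig2)) - kappa * (mu - m0)^2 / (2 * sig2))
  }

  # first M-step from the hard initial partition
  p <- m_step(z)
  if (is.null(p)) collapsed <- TRUE else { w <- p$w; mu <- p$mu; sig2 <- p$sig2 }

  loglik <- NA_real_
  while (!collapsed && it < control$max_iter) {
    it <- it + 1L
    d <- dens(w, mu, sig2)
    rs <- rowSums(d)
    if (any(rs <= 0) || any(!is.finite(rs))) { collapsed <- TRUE; break }
    loglik <- sum(log(rs))
    obj <- loglik + log_prior(mu, sig2)
    if (keep_trace) trace <- c(trace, obj)
    z <- d / rs
    p <- m_step(z)
    if (is.null(p)) { collapsed <- TRUE; break }
    w <- p$w; mu <- p$mu; sig2 <- p$sig2
    if (is.finite(obj_old) &&
        abs(obj - obj_old) <= control$tol * (abs(obj_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!collapsed) {
    d <- dens(w, mu, sig2)
    rs <- rowSums(d)
    if (any(rs <= 0) || any(!is.finite(rs))) collapsed <- TRUE else {
      loglik <- sum(log(rs))
      z <- d / rs
    }
  }
  if (collapsed) {
    fit <- structure(list(g = g, variance_mode = variance_mode, weights = w,
                          means = mu, variances = sig2, loglik = NA_real_,
                          bic = NA_real_, icl = NA_real_, entropy = NA_real_,
                          n = n, n_params = n_mixture_params(g, variance_mode),
                          responsibilities = NULL, converged = FALSE,
                          iterations = it, trace = trace, init = init),
                     class = "mixfit")
    return(fit)
  }
  # label-sort ascending by mean
  o <- order(mu)
  fit <- structure(list(
    g = g, variance_mode = variance_mode,
    weights = w[o], means = mu[o], variances = sig2[o],
    loglik = loglik, bic = NA_real_, icl = NA_real_, entropy = NA_real_,
    n = n, n_params = n_mixture_params(g, variance_mode),
    responsibilities = z[, o, drop = FALSE],
    converged = TRUE, iterations = it, trace = trace, init = init
  ), class = "mixfit")
  score_fit(fit)
}

# free parameters: G means + (G-1) weights + 1 or G variances
n_mixture_params <- function(g, variance_mode) {
  if (variance_mode == "E") 2L * g else 3L * g - 1L
}

#' Score a mixture fit by BIC and ICL
#'
#' Both criteria are on the larger-is-better scale:
#' `BIC = 2 loglik - k log n` and `ICL = BIC - 2 * entropy`, where the
#' classification entropy is `-sum_i sum_g z_ig log z_ig` (with
#' `0 log 0 := 0`). The entropy penalty is non-negative, so `ICL <= BIC`
#' always, with equality under hard classification; ICL thereby favours
#' well-separated genotype clusters over marginally better-fitting but
#' overlapping ones.
#'
#' @param fit A converged `mixfit`.
#' @return The fit with `bic`, `icl` and `entropy` filled in.
#' @export
score_fit <- function(fit) {
  stopifnot(inherits(fit, "mixfit"), isTRUE(fit$converged))
  z <- fit$responsibilities
  fit$bic <- 2 * fit$loglik - fit$n_params * log(fit$n)
  zl <- z * log(z)
  zl[!is.finite(zl)] <- 0
  fit$entropy <- -sum(zl)
  fit$icl <- fit$bic - 2 * fit$entropy
  fit
}

#' Posterior responsibilities at fixed parameters
#'
#' E-step evaluation used when scoring or classifying with externally fixed
#' parameters; exported mainly for diagnostics.
#'
#' @param x Numeric vector of contrasts.
#' @param weights,means,variances Mixture parameters (equal length).
#' @return List with `responsibilities` (length(x) x g) and `loglik`.
#' @export
mixture_posterior <- function(x, weights, means, variances) {
  g <- length(weights)
  d <- vapply(seq_len(g), function(k) {
    weights[k] * stats::dnorm(x, means[k], sqrt(variances[k]))
  }, numeric(length(x)))
  d <- matrix(d, length(x), g)
  rs <- rowSums(d)
  list(responsibilities = d / rs, loglik = sum(log(rs)))
}

#' @export
print.mixfit <- function(x, ...) {
  cat(sprintf("<mixfit> g = %d, mode = %s, n = %d, converged = %s\n",
              x$g, x$variance_mode, x$n, x$converged))
  if (isTRUE(x$converged)) {
    cat(sprintf("  loglik %.3f  BIC %.3f  ICL %.3f\n", x$loglik, x$bic, x$icl))
    cat("  means: ", paste(sprintf("%.3f", x$means), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a mixture fit into one row per cluster
#'
#' @param x A `mixfit`.
#' @param ... Unused.
#' @return Tibble with `cluster`, `weight`, `mean`, `variance`, `size`
#'   (posterior-expected count).
#' @export
tidy.mixfit <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$g),
    weight = x$weights,
    mean = x$means,
    variance = x$variances,
    size = if (is.null(x$responsibilities)) NA_real_ else colSums(x$responsibilities)
  )
}

#' One-row summary of a mixture fit
#'
#' @param x A `mixfit`.
#' @param ... Unused.
#' @return Tibble with `g`, `variance_mode`, `n`, `loglik`, `bic`, `icl`,
#'   `entropy`, `n_params`, `converged`, `iterations`.
#' @export
glance.mixfit <- function(x, ...) {
  tibble::tibble(
    g = x$g, variance_mode = x$variance_mode, n = x$n,
    loglik = x$loglik, bic = x$bic, icl = x$icl, entropy = x$entropy,
    n_params = x$n_params, converged = x$converged, iterations = x$iterations
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
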