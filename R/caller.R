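#' Reference contrast means per dosage
#'
#' Cluster means at markers showing every possible genotype cluster are
#' remarkably stable across markers; their per-dosage averages serve as
#' reference contrast means for labelling clusters at markers that show fewer
#' clusters. The shipped defaults are the published estimates from a large
#' Atlantic salmon panel: -1.76 (BB), 0.16 (AB), 1.94 (AA) for diploids and
#' -1.97 (BBB), -0.50 (ABB), 0.75 (AAB), 2.14 (AAA) for triploids. They can
#' be re-estimated for any dataset with [estimate_reference_means()].
#'
#' @param ploidy 2 or 3.
#' @return Ascending numeric vector of `ploidy + 1` contrast means, one per
#'   dosage (count of A alleles) `0..ploidy`.
#' @export
reference_means <- function(ploidy) {
  if (ploidy == 2) return(c(-1.76, 0.16, 1.94))
  if (ploidy == 3) return(c(-1.97, -0.50, 0.75, 2.14))
  stop("default reference means are shipped for ploidy 2 and 3 only")
}

#' Re-estimate reference contrast means from called markers
#'
#' Averages fitted cluster means per dosage over markers whose selected
#' cluster count equals `ploidy + 1` (where the left-to-right rank rule makes
#' the dosage labels unambiguous).
#'
#' @param calls A `genocall` object from [call_genotypes()].
#' @return Ascending numeric vector of `ploidy + 1` reference means.
#' @export
estimate_reference_means <- function(calls) {
  ploidy <- calls$ploidy
  full <- purrr::keep(calls$fits, ~ !is.null(.x) && .x$g == ploidy + 1)
  if (!length(full)) stop("no marker with the maximum cluster count; cannot estimate reference means")
  m <- vapply(full, function(f) f$means, numeric(ploidy + 1))
  rowMeans(m)
}

#' Select the best mixture model for a marker
#'
#' For each cluster count the better of the two variance structures (by ICL)
#' is kept; the overall winner classifies the marker. The marker-quality
#' statistic `delta_icl` is the ICL gap between the best and second-best
#' cluster counts: large gaps mean the cluster count is unambiguous. Ties go
#' to the smaller cluster count. When only one cluster count is feasible the
#' gap is undefined and stored as `Inf` (such markers are filtered by call
#' rate or mapping collisions instead, never by `delta_icl` alone).
#'
#' @param fits List of `mixfit` objects (non-converged ones are ignored).
#' @return List with `best` (a `mixfit`), `delta_icl`, and `icl_by_g` (named
#'   numeric, best ICL per cluster count); `NULL` if no fit converged.
#' @export
select_best_model <- function(fits) {
  fits <- purrr::keep(fits, ~ inherits(.x, "mixfit") && isTRUE(.x$converged))
  if (!length(fits)) return(NULL)
  gs <- vapply(fits, function(f) as.integer(f$g), integer(1))
  icls <- vapply(fits, `[[`, numeric(1), "icl")
  by_g <- vapply(split(seq_along(fits), gs), function(i) max(icls[i]), numeric(1))
  g_levels <- as.integer(names(by_g))
  best_g <- g_levels[order(-by_g, g_levels)][1]   # tie -> smaller g
  cand <- which(gs == best_g)
  best <- fits[[cand[which.max(icls[cand])]]]
  delta <- if (length(by_g) < 2) Inf else by_g[as.character(best_g)] - max(by_g[g_levels != best_g])
  list(best = best, delta_icl = unname(delta), icl_by_g = by_g)
}

#' Map fitted clusters to allele dosages
#'
#' With the maximum cluster count (`g = ploidy + 1`) the rank rule applies:
#' the lowest-contrast cluster is the all-B genotype (dosage 0), the next
#' dosage 1, and so on. With fewer clusters each fitted cluster mean is
#' matched to the nearest reference contrast mean; if two clusters collide on
#' the same reference mean the locus is ambiguous and the whole marker is a
#' no-call.
#'
#' @param fit A `mixfit` with ascending means.
#' @param reference Ascending vector of `ploidy + 1` reference means.
#' @return Integer vector of dosages (one per cluster), or `NULL` when the
#'   locus cannot be mapped (locus no-call).
#' @export
map_clusters_to_dosage <- function(fit, reference) {
  ploidy <- length(reference) - 1L
  if (fit$g == ploidy + 1L) return(0:ploidy)
  dos <- vapply(fit$means, function(m) which.min(abs(reference - m)) - 1L,
                integer(1))
  if (anyDuplicated(dos)) return(NULL)
  dos
}

#' Classify samples from a fitted mixture
#'
#' Each sample is assigned the cluster with the highest posterior membership
#' probability (ties to the lower-contrast cluster); the call uncertainty is
#' one minus that probability. Calls whose uncertainty exceeds the threshold
#' (strictly; exactly at the threshold is still called) become no-calls.
#' Single-cluster markers have zero uncertainty by construction and rely on
#' the reference mapping alone.
#'
#' @param fit A converged `mixfit`.
#' @param mapping Cluster-to-dosage map from [map_clusters_to_dosage()].
#' @param uncertainty_threshold No-call threshold, default 0.15.
#' @return List with `dosage` (integer, `NA` = no-call) and `uncertainty`,
#'   both of length `fit$n`.
#' @export
call_samples <- function(fit, mapping, uncertainty_threshold = 0.15) {
  z <- fit$responsibilities
  cl <- max.col(z, ties.method = "first")   # first = lower-contrast cluster
  pmax_ <- z[cbind(seq_len(nrow(z)), cl)]
  unc <- 1 - pmax_
  dosage <- mapping[cl]
  # strictly "exceeds": a call exactly at the threshold is kept (the 1e-12
  # slack guards the boundary against floating-point round-off)
  dosage[unc - uncertainty_threshold > 1e-12] <- NA_integer_
  list(dosage = as.integer(dosage), uncertainty = unc)
}

#' Call genotypes for one marker
#'
#' Runs the whole per-marker procedure: enumerate the candidate models for
#' the ploidy, seed each from the allele-frequency-informed partition, fit by
#' MAP-EM, score by ICL, pick the winner, map clusters to dosages through the
#' reference means, and classify samples with the uncertainty rule.
#'
#' @param contrasts Numeric vector of contrasts, `NA` = missing cell.
#' @param ploidy 2 or 3.
#' @param reference Reference contrast means (default [reference_means()]).
#' @param control An [em_control()].
#' @param uncertainty_threshold Per-call no-call threshold (default 0.15).
#' @return List of class `marker_call`: `fit`, `delta_icl`, `icl_by_g`,
#'   `mapping` (or `NULL` for a locus no-call), `dosage` and `uncertainty`
#'   aligned with `contrasts`, `call_rate`, `locus_nocall`, `failed`.
#' @export
call_marker <- function(contrasts, ploidy, reference = reference_means(ploidy),
                        control = em_control(), uncertainty_threshold = 0.15) {
  n_total <- length(contrasts)
  obs <- which(is.finite(contrasts))
  empty <- list(fit = NULL, delta_icl = NA_real_, icl_by_g = NULL,
                mapping = NULL, dosage = rep(NA_integer_, n_total),
                uncertainty = rep(NA_real_, n_total), call_rate = 0,
                locus_nocall = FALSE, failed = TRUE)
  class(empty) <- "marker_call"
  if (length(obs) < 2) return(empty)
  x <- contrasts[obs]
  fits <- list()
  for (g in seq_len(ploidy + 1)) {
    if (length(x) < g) next
    init <- initial_partition(x, ploidy, g, reference)
    for (mode in c("E", "V")) {
      fits[[length(fits) + 1L]] <-
        fit_contrast_mixture(x, g, mode, init = init, control = control)
    }
  }
  sel <- select_best_model(fits)
  if (is.null(sel)) return(empty)
  mapping <- map_clusters_to_dosage(sel$best, reference)
  out <- empty
  out$failed <- FALSE
  out$fit <- sel$best
  out$delta_icl <- sel$delta_icl
  out$icl_by_g <- sel$icl_by_g
  out$mapping <- mapping
  if (is.null(mapping)) {
    out$locus_nocall <- TRUE
    return(out)
  }
  cs <- call_samples(sel$best, mapping, uncertainty_threshold)
  out$dosage[obs] <- cs$dosage
  out$uncertainty[obs] <- cs$uncertainty
  out$call_rate <- sum(!is.na(out$dosage)) / n_total
  out
}

#' Call genotypes for a whole signal set
#'
#' Applies [call_marker()] to every marker of a long contrast tibble and
#' collects genotypes plus per-marker QC.
#'
#' @param signals Tibble with `marker_id`, `sample_id`, `contrast` (e.g. from
#'   [read_normalized_summary()] or [simulate_dataset()]).
#' @param ploidy 2 or 3.
#' @param reference Reference contrast means.
#' @param control An [em_control()].
#' @param uncertainty_threshold Per-call no-call threshold.
#' @param keep_fits Keep the per-marker `mixfit` objects (needed by
#'   [estimate_reference_means()] and [plot_marker_fit()]).
#' @return Object of class `genocall`: `genotypes` tibble (`marker_id`,
#'   `sample_id`, `dosage`, `uncertainty`), `markers` QC tibble (`marker_id`,
#'   `n_clusters`, `variance_mode`, `icl`, `delta_icl`, `call_rate`,
#'   `locus_nocall`, `failed`), `ploidy`, and optionally `fits`.
#' @export
call_genotypes <- function(signals, ploidy, reference = reference_means(ploidy),
                           control = em_control(), uncertainty_threshold = 0.15,
                           keep_fits = TRUE) {
  m <- contrast_matrix(signals)
  markers <- rownames(m)
  samples <- colnames(m)
  dosage <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  uncert <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  qc <- vector("list", length(markers))
  fits <- if (keep_fits) vector("list", length(markers)) else NULL
  for (i in seq_along(markers)) {
    mc <- call_marker(m[i, ], ploidy, reference, control, uncertainty_threshold)
    dosage[i, ] <- mc$dosage
    uncert[i, ] <- mc$uncertainty
    if (keep_fits) fits[[i]] <- mc$fit
    qc[[i]] <- tibble::tibble(
      marker_id = markers[i],
      n_clusters = if (is.null(mc$fit)) NA_integer_ else mc$fit$g,
      variance_mode = if (is.null(mc$fit)) NA_character_ else mc$fit$variance_mode,
      icl = if (is.null(mc$fit)) NA_real_ else mc$fit$icl,
      delta_icl = mc$delta_icl,
      call_rate = mc$call_rate,
      locus_nocall = mc$locus_nocall,
      failed = mc$failed
    )
  }
  genotypes <- tibble::tibble(
    marker_id = rep(markers, times = length(samples)),
    sample_id = rep(samples, each = length(markers)),
    dosage = as.integer(dosage),
    uncertainty = as.vector(uncert)
  )
  if (keep_fits) names(fits) <- markers
  structure(list(genotypes = genotypes, markers = dplyr::bind_rows(qc),
                 ploidy = as.integer(ploidy), fits = fits),
            class = "genocall")
}

#' @export
print.genocall <- function(x, ...) {
  cat(sprintf("<genocall> ploidy %d: %d markers x %d samples\n", x$ploidy,
              nrow(x$markers), length(unique(x$genotypes$sample_id))))
  cat(sprintf("  mean marker call rate %.3f; %d locus no-calls; %d failed\n",
              mean(x$markers$call_rate), sum(x$markers$locus_nocall),
              sum(x$markers$failed)))
  invisible(x)
}

#' Tidy genotype calls into one row per marker x sample
#'
#' @param x A `genocall`.
#' @param ... Unused.
#' @return The `genotypes` tibble.
#' @export
tidy.genocall <- function(x, ...) x$genotypes

#' One-row summary of a genotype call set
#'
#' @param x A `genocall`.
#' @param ... Unused.
#' @return Tibble with marker/sample counts, mean call rate, no-call counts.
#' @export
glance.genocall <- function(x, ...) {
  tibble::tibble(
    ploidy = x$ploidy,
    n_markers = nrow(x$markers),
    n_samples = length(unique(x$genotypes$sample_id)),
    mean_call_rate = mean(x$markers$call_rate),
    n_locus_nocall = sum(x$markers$locus_nocall),
    n_failed = sum(x$markers$failed)
  )
}

#' Filter markers by delta-ICL and call rate
#'
#' Retains markers with `delta_icl` strictly greater than `delta_icl_min`
#' (so a marker exactly at the threshold is removed) and `call_rate >=
#' call_rate_min`. Markers with only one feasible cluster count carry
#' `delta_icl = Inf` and are never removed by the delta-ICL rule alone.
#'
#' @param x A `genocall` or a marker QC tibble with `delta_icl`, `call_rate`.
#' @param delta_icl_min Strict lower bound on `delta_icl` (default 0).
#' @param call_rate_min Non-strict lower bound on `call_rate` (default 0).
#' @return Same type as `x`, restricted to retained markers, with attribute
#'   `n_removed`.
#' @export
filter_markers <- function(x, delta_icl_min = 0, call_rate_min = 0) {
  qc <- if (inherits(x, "genocall")) x$markers else x
  keep <- !is.na(qc$delta_icl) & qc$delta_icl > delta_icl_min &
    qc$call_rate >= call_rate_min
  if ("locus_nocall" %in% names(qc)) keep <- keep & !qc$locus_nocall
  kept_ids <- qc$marker_id[keep]
  if (inherits(x, "genocall")) {
    out <- x
    out$markers <- qc[keep, ]
    out$genotypes <- dplyr::filter(x$genotypes, .data$marker_id %in% kept_ids)
    if (!is.null(out$fits)) out$fits <- out$fits[kept_ids]
  } else {
    out <- qc[keep, ]
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-sample call rates
#'
#' @param genotypes A `genocall` or a long genotype tibble with `sample_id`,
#'   `dosage`.
#' @return Tibble with `sample_id` and `call_rate` (called markers / total
#'   markers for that sample).
#' @export
sample_call_rates <- function(genotypes) {
  g <- if (inherits(genotypes, "genocall")) genotypes$genotypes else genotypes
  dplyr::summarise(dplyr::group_by(g, .data$sample_id),
                   call_rate = mean(!is.na(.data$dosage)), .groups = "drop")
}

#' Write per-marker QC to a TSV
#'
#' @param calls A `genocall` or marker QC tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_qc <- function(calls, path) {
  qc <- if (inherits(calls, "genocall")) calls$markers else calls
  readr::write_tsv(qc, path, na = "NA", progress = FALSE)
  invisible(path)
}
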