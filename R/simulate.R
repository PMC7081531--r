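#' Configuration for the allele-signal and pedigree simulator
#'
#' Defines the study conditions the simulator reproduces: diploid parents in
#' Hardy-Weinberg proportions, triploid offspring formed by second-polar-body
#' retention (the mother transmits a sister-chromatid pair, identical except
#' distal to crossovers; the father one allele), and per-marker contrast
#' clusters centred near the reference means with marker-specific shifts and
#' optional cluster-specific (heteroscedastic) noise.
#'
#' The meiosis model is a simple switch process: per chromosome arm the
#' chiasma count is Poisson(`crossover_rate`) with positions uniform on the
#' arm, and each chiasma toggles the hom/het state of the retained chromatid
#' pair distal to it with probability `chromatid_switch_prob`. The resulting
#' het fraction at map distance d from the centromere has the closed form
#' `(1 - exp(-2 * s * lambda(d))) / 2` (see [true_het_fraction()]); that
#' curve, not any biological map, is the ground truth the recombination
#' profile is checked against.
#'
#' @param n_markers Number of SNP markers.
#' @param n_mothers,n_fathers,offspring_per_cross Full-factorial cross
#'   design: every mother x father pair yields `offspring_per_cross`
#'   offspring.
#' @param offspring_ploidy 3 (induced triploids) or 2 (ordinary diploids).
#' @param maf_range Support of the uniform minor-allele-frequency draw.
#' @param marker_shift_sd SD of the per-marker shift added to all cluster
#'   means (contrast units).
#' @param cluster_sd_range Uniform support for cluster SDs (contrast units).
#' @param heteroscedastic_fraction Fraction of markers whose clusters get
#'   independent SDs (the rest share one SD).
#' @param noisy_fraction,noisy_sd Fraction of markers injected with an
#'   inflated cluster SD, emulating poorly separating assays.
#' @param signal_size Fixed sum `a_signal + b_signal` used to de-transform
#'   contrasts back to a pair of positive signals.
#' @param genotype_error_rate Probability that a cell's dosage is replaced by
#'   a uniformly different dosage before signal generation (the truth set
#'   keeps the original).
#' @param error_mode `"dosage"` (miscluster-like, default) or `"signal"`
#'   (the erroneous dosage only shifts the signal mean; identical effect on
#'   calling, kept for symmetry with the dosage bookkeeping).
#' @param n_chromosomes,chromosome_length_bp,centromere_position_bp Map
#'   layout; markers are spread evenly over chromosomes at uniform positions.
#' @param crossover_rate Mean chiasma count per chromosome arm per meiosis.
#' @param chromatid_switch_prob Probability a chiasma toggles the retained
#'   pair's hom/het state.
#' @param seed Integer seed; fully determines the simulated dataset
#'   (R's default Mersenne-Twister RNG).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 1000,
                       n_mothers = 10, n_fathers = 10, offspring_per_cross = 3,
                       offspring_ploidy = 3,
                       maf_range = c(0.05, 0.5),
                       marker_shift_sd = 0.15,
                       cluster_sd_range = c(0.08, 0.25),
                       heteroscedastic_fraction = 0.5,
                       noisy_fraction = 0, noisy_sd = 0.6,
                       signal_size = 2000,
                       genotype_error_rate = 0.005,
                       error_mode = c("dosage", "signal"),
                       n_chromosomes = 5,
                       chromosome_length_bp = 1e8,
                       centromere_position_bp = 5e7,
                       crossover_rate = 1.0,
                       chromatid_switch_prob = 0.5,
                       seed = 1L) {
  error_mode <- match.arg(error_mode)
  cfg <- list(n_markers = n_markers, n_mothers = n_mothers,
              n_fathers = n_fathers, offspring_per_cross = offspring_per_cross,
              offspring_ploidy = offspring_ploidy, maf_range = maf_range,
              marker_shift_sd = marker_shift_sd,
              cluster_sd_range = cluster_sd_range,
              heteroscedastic_fraction = heteroscedastic_fraction,
              noisy_fraction = noisy_fraction, noisy_sd = noisy_sd,
              signal_size = signal_size,
              genotype_error_rate = genotype_error_rate,
              error_mode = error_mode,
              n_chromosomes = n_chromosomes,
              chromosome_length_bp = chromosome_length_bp,
              centromere_position_bp = centromere_position_bp,
              crossover_rate = crossover_rate,
              chromatid_switch_prob = chromatid_switch_prob,
              seed = as.integer(seed))
  stopifnot(cfg$offspring_ploidy %in% c(2, 3),
            all(cfg$cluster_sd_range > 0),
            cfg$genotype_error_rate >= 0, cfg$genotype_error_rate <= 1,
            cfg$chromatid_switch_prob >= 0, cfg$chromatid_switch_prob <= 1,
            cfg$heteroscedastic_fraction >= 0, cfg$heteroscedastic_fraction <= 1,
            cfg$noisy_fraction >= 0, cfg$noisy_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a marker map
#'
#' Spreads markers evenly across chromosomes at uniform random positions.
#'
#' @param config A [sim_config()].
#' @return Tibble with `marker_id`, `chromosome`, `position`, sorted by
#'   `(chromosome, position)`.
#' @export
simulate_marker_map <- function(config) {
  n <- config$n_markers
  chr <- sprintf("chr%02d", rep_len(seq_len(config$n_chromosomes), n))
  chr <- sort(chr)
  pos <- unlist(lapply(split(seq_len(n), chr), function(i) {
    sort(ceiling(stats::runif(length(i), 1, config$chromosome_length_bp)))
  }), use.names = FALSE)
  tibble::tibble(marker_id = sprintf("M%05d", seq_len(n)),
                 chromosome = chr, position = pos)
}

#' Simulate diploid parents in Hardy-Weinberg proportions
#'
#' Draws a minor-allele frequency per marker and two Bernoulli(p) haplotypes
#' per parent, giving binomial(2, p) dosages.
#'
#' @param config A [sim_config()].
#' @return List: `maf` (per-marker A-allele frequency), `mother_haps` and
#'   `father_haps` (each a list of two markers x parents 0/1 matrices),
#'   `dosage` (markers x all-parents matrix, mothers then fathers).
#' @export
simulate_parents <- function(config) {
  n <- config$n_markers
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  draw <- function(n_ind, prefix) {
    h1 <- matrix(stats::rbinom(n * n_ind, 1, maf), n, n_ind)
    h2 <- matrix(stats::rbinom(n * n_ind, 1, maf), n, n_ind)
    colnames(h1) <- colnames(h2) <- sprintf("%s%03d", prefix, seq_len(n_ind))
    list(h1, h2)
  }
  mh <- draw(config$n_mothers, "MOT")
  fh <- draw(config$n_fathers, "FAT")
  dosage <- cbind(mh[[1]] + mh[[2]], fh[[1]] + fh[[2]])
  rownames(dosage) <- sprintf("M%05d", seq_len(n))
  list(maf = maf, mother_haps = mh, father_haps = fh, dosage = dosage)
}

#' Simulate one triploid meiosis (second-polar-body retention)
#'
#' Draws chiasmata per chromosome arm, toggles the hom/het state of the
#' retained maternal chromatid pair distal to each chiasma with the
#' configured probability, and assembles the offspring dosage as maternal
#' A-count plus one paternal allele.
#'
#' @param mother_h1,mother_h2,father_h1,father_h2 0/1 haplotype vectors over
#'   markers (map order).
#' @param map Marker map tibble aligned with the haplotype vectors.
#' @param config A [sim_config()].
#' @return List: `dosage` (0..3 per marker), `maternal_state` (`"hom"`/
#'   `"het"` per marker), `maternal_dosage`, `crossovers` (tibble of chiasma
#'   positions and whether each toggled the state).
#' @export
simulate_triploid_offspring <- function(mother_h1, mother_h2,
                                        father_h1, father_h2, map, config) {
  n <- nrow(map)
  het_state <- logical(n)
  xov <- list()
  cen <- config$centromere_position_bp
  len <- config$chromosome_length_bp
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position[idx]
    for (arm in c("p", "q")) {
      arm_len <- if (arm == "p") cen else len - cen
      if (arm_len <= 0) next
      k <- stats::rpois(1, config$crossover_rate)
      if (k == 0) next
      d_chiasma <- stats::runif(k, 0, arm_len)      # distance from centromere
      flips <- stats::runif(k) < config$chromatid_switch_prob
      d_marker <- if (arm == "p") cen - pos else pos - cen
      on_arm <- d_marker > 0
      # parity of toggling chiasmata proximal to each marker
      n_flips <- colSums(outer(d_chiasma[flips], d_marker, "<"))
      het_state[idx[on_arm]] <- xor(het_state[idx[on_arm]],
                                    (n_flips[on_arm] %% 2) == 1)
      xov[[length(xov) + 1L]] <- tibble::tibble(
        chromosome = chr, arm = arm,
        position = if (arm == "p") cen - d_chiasma else cen + d_chiasma,
        toggled = flips)
    }
  }
  base <- sample(1:2, 1)
  base_allele <- if (base == 1) mother_h1 else mother_h2
  maternal <- ifelse(het_state, mother_h1 + mother_h2, 2L * base_allele)
  paternal <- ifelse(stats::runif(n) < 0.5, father_h1, father_h2)
  list(dosage = as.integer(maternal + paternal),
       maternal_state = ifelse(het_state, "het", "hom"),
       maternal_dosage = as.integer(maternal),
       crossovers = dplyr::bind_rows(xov))
}

#' Closed-form true heterozygous-maternal-inheritance fraction
#'
#' Under the simulator's switch-process meiosis model, a locus at map
#' distance `d` from the centromere on an arm of length `L` sees
#' `N ~ Poisson(rate * d / L)` chiasmata, each toggling the retained pair's
#' state independently with probability `s`; the probability of ending
#' heterozygous is `(1 - exp(-2 * s * rate * d / L)) / 2`.
#'
#' @param position Marker position(s) in bp.
#' @param config A [sim_config()].
#' @return Numeric vector of true het fractions.
#' @export
true_het_fraction <- function(position, config) {
  cen <- config$centromere_position_bp
  len <- config$chromosome_length_bp
  arm_len <- ifelse(position < cen, cen, len - cen)
  d <- abs(position - cen)
  lambda <- config$crossover_rate * d / arm_len
  (1 - exp(-2 * config$chromatid_switch_prob * lambda)) / 2
}

#' Simulate allele signals from true dosages
#'
#' Per marker: a common shift `~ N(0, marker_shift_sd)` is added to the
#' reference cluster means; cluster SDs are drawn from `cluster_sd_range`
#' (shared across clusters for equal-variance markers, independent for the
#' heteroscedastic fraction); injected noisy markers use `noisy_sd` for every
#' cluster. With probability `genotype_error_rate` a cell's dosage is
#' replaced by a uniformly different dosage before its contrast is drawn.
#' Contrasts are de-transformed into positive `a_signal`/`b_signal` pairs
#' summing to `signal_size`.
#'
#' @param dosage Markers x samples integer matrix of true dosages (`NA` kept
#'   missing).
#' @param ploidy Ploidy of the dosages.
#' @param config A [sim_config()].
#' @param noisy Logical per-marker vector of injected-noisy flags; drawn from
#'   `config$noisy_fraction` when `NULL`.
#' @return List: `signals` (long tibble with `marker_id`, `sample_id`,
#'   `a_signal`, `b_signal`, `contrast`), `noisy` (per-marker flags),
#'   `errors` (logical matrix of injected dosage errors), `marker_params`
#'   (tibble of shifts and SDs).
#' @export
simulate_signals <- function(dosage, ploidy, config, noisy = NULL) {
  ref <- reference_means(ploidy)
  n_mark <- nrow(dosage)
  n_samp <- ncol(dosage)
  if (is.null(noisy)) noisy <- stats::runif(n_mark) < config$noisy_fraction
  shift <- stats::rnorm(n_mark, 0, config$marker_shift_sd)
  hetero <- stats::runif(n_mark) < config$heteroscedastic_fraction
  sds <- matrix(stats::runif(n_mark * (ploidy + 1),
                             config$cluster_sd_range[1],
                             config$cluster_sd_range[2]),
                n_mark, ploidy + 1)
  sds[!hetero, ] <- sds[!hetero, 1]
  sds[noisy, ] <- config$noisy_sd
  err <- matrix(stats::runif(n_mark * n_samp) < config$genotype_error_rate,
                n_mark, n_samp) & !is.na(dosage)
  observed <- dosage
  if (any(err)) {
    shiftd <- 1L + floor(stats::runif(sum(err)) * ploidy)  # 1..ploidy
    observed[err] <- (dosage[err] + shiftd) %% (ploidy + 1L)
  }
  mu <- matrix(shift, n_mark, n_samp) +
    matrix(ref[observed + 1L], n_mark, n_samp)
  sd_cell <- matrix(sds[cbind(rep(seq_len(n_mark), n_samp),
                              as.vector(observed) + 1L)], n_mark, n_samp)
  contrast <- matrix(stats::rnorm(n_mark * n_samp, as.vector(mu),
                                  as.vector(sd_cell)), n_mark, n_samp)
  contrast[is.na(observed)] <- NA_real_
  b <- config$signal_size / (1 + 2^contrast)
  a <- config$signal_size - b
  signals <- tibble::tibble(
    marker_id = rep(rownames(dosage), times = n_samp),
    sample_id = rep(colnames(dosage), each = n_mark),
    a_signal = as.vector(a),
    b_signal = as.vector(b),
    contrast = as.vector(contrast)
  )
  list(signals = signals, noisy = noisy, errors = err,
       marker_params = tibble::tibble(marker_id = rownames(dosage),
                                      shift = shift, noisy = noisy,
                                      heteroscedastic = hetero))
}

#' Simulate a complete triploid (or diploid) family study
#'
#' Orchestrates the whole generative model: marker map, Hardy-Weinberg
#' diploid parents, a full-factorial cross design, triploid offspring by
#' second-polar-body retention (or ordinary diploid offspring when
#' `offspring_ploidy = 2`), and allele signals for both generations. The
#' seed in the config fully determines the output.
#'
#' @param config A [sim_config()].
#' @return List of class `triosim`: `config`, `map`, `maf`, `pedigree`
#'   (`offspring_id`, `mother_id`, `father_id`), `parent_dosage` and
#'   `offspring_dosage` truth matrices, `maternal_state` (markers x
#'   offspring, triploid only), `crossovers`, `parent_signals` and
#'   `offspring_signals` tibbles, `noisy_markers`, `signal_errors`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- simulate_marker_map(config)
  par <- simulate_parents(config)
  mothers <- colnames(par$mother_haps[[1]])
  fathers <- colnames(par$father_haps[[1]])
  ped <- tidyr::expand_grid(mother_id = mothers, father_id = fathers,
                            rep = seq_len(config$offspring_per_cross))
  ped$offspring_id <- sprintf("OFF%04d", seq_len(nrow(ped)))
  ped <- dplyr::select(ped, "offspring_id", "mother_id", "father_id")

  n <- config$n_markers
  n_off <- nrow(ped)
  off_dosage <- matrix(NA_integer_, n, n_off,
                       dimnames = list(map$marker_id, ped$offspring_id))
  maternal_state <- NULL
  crossovers <- NULL
  if (config$offspring_ploidy == 3) {
    maternal_state <- matrix(NA_character_, n, n_off,
                             dimnames = list(map$marker_id, ped$offspring_id))
    xovs <- vector("list", n_off)
    for (k in seq_len(n_off)) {
      mi <- match(ped$mother_id[k], mothers)
      fi <- match(ped$father_id[k], fathers)
      off <- simulate_triploid_offspring(
        par$mother_haps[[1]][, mi], par$mother_haps[[2]][, mi],
        par$father_haps[[1]][, fi], par$father_haps[[2]][, fi], map, config)
      off_dosage[, k] <- off$dosage
      maternal_state[, k] <- off$maternal_state
      if (nrow(off$crossovers)) {
        xovs[[k]] <- dplyr::mutate(off$crossovers,
                                   offspring_id = ped$offspring_id[k])
      }
    }
    crossovers <- dplyr::bind_rows(xovs)
  } else {
    for (k in seq_len(n_off)) {
      mi <- match(ped$mother_id[k], mothers)
      fi <- match(ped$father_id[k], fathers)
      mat <- ifelse(stats::runif(n) < 0.5,
                    par$mother_haps[[1]][, mi], par$mother_haps[[2]][, mi])
      pat <- ifelse(stats::runif(n) < 0.5,
                    par$father_haps[[1]][, fi], par$father_haps[[2]][, fi])
      off_dosage[, k] <- as.integer(mat + pat)
    }
  }

  noisy <- stats::runif(n) < config$noisy_fraction
  off_sig <- simulate_signals(off_dosage, config$offspring_ploidy, config,
                              noisy = noisy)
  par_sig <- simulate_signals(par$dosage, 2, config, noisy = noisy)

  structure(list(
    config = config, map = map, maf = par$maf, pedigree = ped,
    parent_dosage = par$dosage, offspring_dosage = off_dosage,
    maternal_state = maternal_state, crossovers = crossovers,
    parent_signals = par_sig$signals, offspring_signals = off_sig$signals,
    noisy_markers = map$marker_id[noisy],
    signal_errors = list(offspring = off_sig$errors, parents = par_sig$errors)
  ), class = "triosim")
}

#' @export
print.triosim <- function(x, ...) {
  cat(sprintf("<triosim> %d markers, %d mothers x %d fathers, %d %s offspring (seed %d)\n",
              x$config$n_markers, x$config$n_mothers, x$config$n_fathers,
              nrow(x$pedigree),
              if (x$config$offspring_ploidy == 3) "triploid" else "diploid",
              x$config$seed))
  invisible(x)
}

#' Long truth-genotype tibble from a simulated dataset
#'
#' @param sim A `triosim`.
#' @param who `"offspring"` or `"parents"`.
#' @return Tibble with `marker_id`, `sample_id`, `dosage`.
#' @export
sim_truth_genotypes <- function(sim, who = c("offspring", "parents")) {
  who <- match.arg(who)
  m <- if (who == "offspring") sim$offspring_dosage else sim$parent_dosage
  tibble::tibble(marker_id = rep(rownames(m), times = ncol(m)),
                 sample_id = rep(colnames(m), each = nrow(m)),
                 dosage = as.integer(m))
}

#' Write a simulated dataset to disk
#'
#' Writes the offspring and parent signals in both supported dialects
#' (normalized-summary TSV and long CSV), the truth genotypes, the pedigree,
#' the marker map, and the noisy-marker truth class.
#'
#' @param sim A `triosim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_normalized_summary(sim$offspring_signals,
                           file.path(dir, "offspring.normalized-summary.txt"))
  write_normalized_summary(sim$parent_signals,
                           file.path(dir, "parents.normalized-summary.txt"))
  readr::write_csv(sim$offspring_signals, file.path(dir, "offspring_signals.csv"),
                   progress = FALSE)
  readr::write_csv(sim$parent_signals, file.path(dir, "parent_signals.csv"),
                   progress = FALSE)
  write_genotypes(sim_truth_genotypes(sim, "offspring"),
                  file.path(dir, "offspring_truth_genotypes.tsv"))
  write_genotypes(sim_truth_genotypes(sim, "parents"),
                  file.path(dir, "parent_truth_genotypes.tsv"))
  readr::write_tsv(sim$pedigree, file.path(dir, "pedigree.tsv"), progress = FALSE)
  readr::write_tsv(sim$map, file.path(dir, "marker_map.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(marker_id = sim$noisy_markers),
                   file.path(dir, "noisy_markers.tsv"), progress = FALSE)
  invisible(dir)
}
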