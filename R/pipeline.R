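#' Run the full simulate / call / filter / assign / sex / recombination
#' pipeline
#'
#' Orchestrates the stages as one reproducible run driven by a single config:
#' simulate (or read) allele signals, call genotypes for parents and
#' offspring, filter markers by delta-ICL and call rate, assign parents by
#' exclusion ratio, predict parental sex, and (for triploids) build the
#' maternal recombination profile. Every run writes a provenance record
#' (config echo, package version, seed) and a JSON summary with the counts a
#' study report needs: markers retained per filter, offspring assigned 0/1/2
#' parents, conflicts.
#'
#' @param config A [sim_config()], a YAML file path with its fields (top
#'   level or under a `simulate:` key, with optional `call:`, `assign:`,
#'   `recomb:` sections), or a named list of overrides.
#' @param out_dir Output directory for TSV artifacts and `summary.json`.
#' @param delta_icl_min,parent_call_rate_min QC filter for parentage
#'   assignment (defaults 150, 0.95).
#' @param er_threshold,mother_er_threshold Assignment and sex thresholds
#'   (defaults 0.002, 0.02).
#' @param recomb_min_trios,recomb_delta_icl_min Recombination-profile
#'   thresholds (defaults 50 and 50).
#' @return Invisibly, a list with all stage results plus `summary`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         delta_icl_min = 150, parent_call_rate_min = 0.95,
                         er_threshold = 0.002, mother_er_threshold = 0.02,
                         recomb_min_trios = 50, recomb_delta_icl_min = 50) {
  config <- as_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_dataset(config)
  write_dataset(sim, file.path(out_dir, "simulated"))

  off_calls <- call_genotypes(sim$offspring_signals, config$offspring_ploidy,
                              keep_fits = FALSE)
  par_calls <- call_genotypes(sim$parent_signals, 2, keep_fits = FALSE)
  write_genotypes(off_calls$genotypes, file.path(out_dir, "offspring_genotypes.tsv"))
  write_genotypes(par_calls$genotypes, file.path(out_dir, "parent_genotypes.tsv"))
  write_marker_qc(off_calls, file.path(out_dir, "offspring_marker_qc.tsv"))
  write_marker_qc(par_calls, file.path(out_dir, "parent_marker_qc.tsv"))

  par_rate <- dplyr::summarise(
    dplyr::group_by(par_calls$genotypes, .data$marker_id),
    parent_call_rate = mean(!is.na(.data$dosage)), .groups = "drop")
  qc <- dplyr::left_join(off_calls$markers, par_rate, by = "marker_id")
  retained <- qc$marker_id[
    !is.na(qc$delta_icl) & qc$delta_icl > delta_icl_min & !qc$locus_nocall &
      !is.na(qc$parent_call_rate) & qc$parent_call_rate >= parent_call_rate_min]

  off_f <- dplyr::filter(off_calls$genotypes, .data$marker_id %in% retained)
  par_f <- dplyr::filter(par_calls$genotypes, .data$marker_id %in% retained)
  duos <- duo_stats(off_f, par_f, ploidy = config$offspring_ploidy)
  readr::write_tsv(duos, file.path(out_dir, "duo_stats.tsv"), progress = FALSE)

  assigned <- assign_parentage(duos, er_threshold)
  if (config$offspring_ploidy == 3) {
    assigned <- predict_parent_sex(assigned, mother_er_threshold)
  }
  readr::write_tsv(assigned, file.path(out_dir, "assignments.tsv"), progress = FALSE)

  profile <- NULL
  if (config$offspring_ploidy == 3) {
    # conflicted offspring (two "mothers"/"fathers" or > 2 parents) are not
    # usable as trios
    clean <- dplyr::filter(assigned, !.data$conflict, !.data$sex_conflict)
    ped_hat <- dplyr::inner_join(
      dplyr::select(dplyr::filter(clean, .data$sex == "mother"),
                    "offspring_id", mother_id = "candidate_id"),
      dplyr::select(dplyr::filter(clean, .data$sex == "father"),
                    "offspring_id", father_id = "candidate_id"),
      by = "offspring_id", relationship = "one-to-one")
    if (nrow(ped_hat)) {
      trios <- build_trios(off_calls$genotypes, par_calls$genotypes, ped_hat)
      profile <- recomb_profile(trios, sim$map, min_trios = recomb_min_trios,
                                marker_qc = off_calls$markers,
                                delta_icl_min = recomb_delta_icl_min)
      readr::write_tsv(profile, file.path(out_dir, "recomb_profile.tsv"),
                       progress = FALSE)
    }
  }

  n_parents <- dplyr::count(assigned, .data$offspring_id)
  summary <- list(
    n_markers = config$n_markers,
    n_offspring = nrow(sim$pedigree),
    n_markers_retained = length(retained),
    n_markers_removed = config$n_markers - length(retained),
    offspring_with_two_parents = sum(n_parents$n == 2),
    offspring_with_one_parent = sum(n_parents$n == 1),
    offspring_with_no_parent = nrow(sim$pedigree) - nrow(n_parents),
    assignment_conflicts = sum(assigned$conflict),
    sex_conflicts = if ("sex_conflict" %in% names(assigned))
      sum(assigned$sex_conflict) else 0L,
    recomb_markers = if (is.null(profile)) 0L else nrow(profile)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  provenance <- list(package = "triocall",
                     version = as.character(utils::packageVersion("triocall")),
                     seed = config$seed,
                     config = unclass(config),
                     timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, offspring_calls = off_calls,
                 parent_calls = par_calls, duo_stats = duos,
                 assignments = assigned, profile = profile, summary = summary))
}

# Accept a sim_config, a YAML path, or a named list of overrides.
as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (!is.null(config$simulate)) config <- config$simulate
  }
  stopifnot(is.list(config))
  known <- names(formals(sim_config))
  do.call(sim_config, config[intersect(names(config), known)])
}
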