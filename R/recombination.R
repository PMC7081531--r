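#' Deduce the maternal contribution at a marker
#'
#' In a pressure-shock triploid the mother contributes two alleles and the
#' father one. Where the father is homozygous his allele is known, so the
#' maternal two-allele contribution is the offspring dosage minus the
#' paternal A-count: 1 means a heterozygous (AB) maternal pair, 0 or 2 a
#' homozygous one, and anything outside 0..2 is a Mendelian impossibility
#' (a genotyping error).
#'
#' @param offspring_dosage Triploid dosage `0..3` (vectorized).
#' @param father_dosage Homozygous father dosage, 0 or 2 (vectorized); a
#'   heterozygous father is not informative and raises an error.
#' @return Character vector: `"hom"`, `"het"` or `"inconsistent"` (`NA` where
#'   either input is missing).
#' @export
maternal_contribution <- function(offspring_dosage, father_dosage) {
  if (any(father_dosage == 1L, na.rm = TRUE)) {
    stop("not informative: heterozygous father; pre-filter with is_informative()")
  }
  mat <- offspring_dosage - ifelse(father_dosage == 2L, 1L, 0L)
  out <- rep(NA_character_, length(mat))
  out[!is.na(mat) & mat == 1L] <- "het"
  out[!is.na(mat) & (mat == 0L | mat == 2L)] <- "hom"
  out[!is.na(mat) & (mat < 0L | mat > 2L)] <- "inconsistent"
  out
}

#' Is a trio informative for maternal recombination at a marker?
#'
#' Informative means the father is homozygous (his transmitted allele is
#' known) and the mother heterozygous (so her two-allele contribution can be
#' distinguished as hom or het).
#'
#' @param mother_dosage,father_dosage Diploid dosages (vectorized).
#' @return Logical vector (`FALSE` where either is missing).
#' @export
is_informative <- function(mother_dosage, father_dosage) {
  !is.na(mother_dosage) & !is.na(father_dosage) &
    mother_dosage == 1L & (father_dosage == 0L | father_dosage == 2L)
}

#' Assemble per-marker trio genotypes from calls and assignments
#'
#' Joins offspring and parent genotype tibbles with a sexed assignment table
#' into the long trio format used by [trio_er()] and [recomb_profile()].
#'
#' @param offspring,parents Long genotype tibbles or `genocall` objects.
#' @param pedigree Tibble with `offspring_id`, `mother_id`, `father_id`.
#' @return Tibble with `marker_id`, `offspring_id`, `offspring`, `mother`,
#'   `father` dosage columns.
#' @export
build_trios <- function(offspring, parents, pedigree) {
  og <- if (inherits(offspring, "genocall")) offspring$genotypes else offspring
  pg <- if (inherits(parents, "genocall")) parents$genotypes else parents
  o <- dplyr::select(og, "marker_id", offspring_id = "sample_id",
                     offspring = "dosage")
  o <- dplyr::inner_join(o, pedigree, by = "offspring_id")
  p <- dplyr::select(pg, "marker_id", "sample_id", "dosage")
  o <- dplyr::left_join(o, dplyr::rename(p, mother_id = "sample_id",
                                         mother = "dosage"),
                        by = c("marker_id", "mother_id"))
  o <- dplyr::left_join(o, dplyr::rename(p, father_id = "sample_id",
                                         father = "dosage"),
                        by = c("marker_id", "father_id"))
  dplyr::select(o, "marker_id", "offspring_id", "offspring", "mother", "father")
}

#' Maternal heterozygous-inheritance profile along the genome
#'
#' For each marker, over the informative sexed trios (homozygous father,
#' heterozygous mother), counts how often the maternal contribution is
#' heterozygous. Near the centromere recombination is suppressed and the
#' retained sister-chromatid pair is homozygous; the het fraction rises with
#' distance from the centromere, as in gene-centromere mapping. Trios that
#' are Mendelian-impossible at a marker are dropped from both numerator and
#' denominator and tallied in `n_inconsistent`.
#'
#' Optional marker QC filtering mirrors the recommended defaults: delta-ICL
#' strictly above 50 and call rates of at least 0.80 (triploid offspring) and
#' 0.95 (diploid parents).
#'
#' @param trios Tibble from [build_trios()].
#' @param marker_map Tibble with `marker_id`, `chromosome`, `position`;
#'   markers absent from the map are dropped with a warning.
#' @param min_trios Minimum informative trios to retain a marker (default 50).
#' @param marker_qc Optional tibble with `marker_id`, `delta_icl`, and
#'   optionally `call_rate` (offspring) / `parent_call_rate` columns.
#' @param delta_icl_min,offspring_call_rate_min,parent_call_rate_min QC
#'   thresholds applied when `marker_qc` is supplied.
#' @return Tibble of class `recomb_profile`, sorted by `(chromosome,
#'   position)`: `marker_id`, `chromosome`, `position`, `n_informative`,
#'   `n_het_maternal`, `n_inconsistent`, `het_fraction`.
#' @export
recomb_profile <- function(trios, marker_map, min_trios = 50, marker_qc = NULL,
                           delta_icl_min = 50, offspring_call_rate_min = 0.80,
                           parent_call_rate_min = 0.95) {
  if (!is.null(marker_qc)) {
    keep <- marker_qc$marker_id[
      !is.na(marker_qc$delta_icl) & marker_qc$delta_icl > delta_icl_min &
        (if ("call_rate" %in% names(marker_qc))
          marker_qc$call_rate >= offspring_call_rate_min else TRUE) &
        (if ("parent_call_rate" %in% names(marker_qc))
          marker_qc$parent_call_rate >= parent_call_rate_min else TRUE)]
    trios <- dplyr::filter(trios, .data$marker_id %in% keep)
  }
  unmapped <- setdiff(unique(trios$marker_id), marker_map$marker_id)
  if (length(unmapped)) {
    warning(length(unmapped), " marker(s) absent from the map dropped")
    trios <- dplyr::filter(trios, !.data$marker_id %in% unmapped)
  }
  inf <- dplyr::filter(trios, is_informative(.data$mother, .data$father),
                       !is.na(.data$offspring))
  if (!nrow(inf)) {
    out <- tibble::tibble(marker_id = character(), chromosome = character(),
                          position = double(), n_informative = integer(),
                          n_het_maternal = integer(), n_inconsistent = integer(),
                          het_fraction = double())
    class(out) <- c("recomb_profile", class(out))
    return(out)
  }
  inf$state <- maternal_contribution(inf$offspring, inf$father)
  prof <- dplyr::summarise(
    dplyr::group_by(inf, .data$marker_id),
    n_informative = sum(.data$state != "inconsistent"),
    n_het_maternal = sum(.data$state == "het"),
    n_inconsistent = sum(.data$state == "inconsistent"),
    .groups = "drop")
  prof$het_fraction <- prof$n_het_maternal / prof$n_informative
  prof <- dplyr::filter(prof, .data$n_informative >= min_trios)
  prof <- dplyr::inner_join(prof, marker_map, by = "marker_id")
  prof <- dplyr::arrange(prof, .data$chromosome, .data$position)
  prof <- dplyr::relocate(prof, "marker_id", "chromosome", "position")
  class(prof) <- c("recomb_profile", class(prof))
  prof
}

#' Per-mother maternal crossover report
#'
#' For each offspring and chromosome, scans the informative markers in map
#' order and reports transitions between homozygous and heterozygous maternal
#' inheritance, using a simple run-length segmentation: a transition is kept
#' only when the runs on both sides span at least `min_run` informative
#' markers. This is a deterministic extension for inspecting individual
#' meioses, not a genetic-map estimator.
#'
#' @param trios Tibble from [build_trios()].
#' @param marker_map Marker map tibble.
#' @param min_run Minimum informative markers per flanking run (default 5).
#' @return Tibble with `offspring_id`, `chromosome`, `from_state`,
#'   `to_state`, `position_before`, `position_after` per kept transition.
#' @export
maternal_crossover_report <- function(trios, marker_map, min_run = 5) {
  inf <- dplyr::filter(trios, is_informative(.data$mother, .data$father),
                       !is.na(.data$offspring))
  inf$state <- maternal_contribution(inf$offspring, inf$father)
  inf <- dplyr::filter(inf, .data$state != "inconsistent")
  inf <- dplyr::inner_join(inf, marker_map, by = "marker_id")
  inf <- dplyr::arrange(inf, .data$offspring_id, .data$chromosome, .data$position)
  segs <- dplyr::group_modify(
    dplyr::group_by(inf, .data$offspring_id, .data$chromosome),
    function(d, key) {
      r <- rle(d$state)
      if (length(r$lengths) < 2) return(tibble::tibble())
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      keep <- which(r$lengths[-length(r$lengths)] >= min_run &
                      r$lengths[-1] >= min_run)
      if (!length(keep)) return(tibble::tibble())
      tibble::tibble(
        from_state = r$values[keep],
        to_state = r$values[keep + 1],
        position_before = d$position[ends[keep]],
        position_after = d$position[starts[keep + 1]]
      )
    })
  dplyr::ungroup(segs)
}
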