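# Genotype code helpers: dosage = count of A alleles. Diploid 0=BB,1=AB,2=AA;
# triploid 0=BBB .. 3=AAA. Parent genotypes are always diploid (0/1/2).

geno_label <- function(dosage, ploidy) {
  vapply(dosage, function(d) {
    if (is.na(d)) return("NA")
    paste0(strrep("A", d), strrep("B", ploidy - d))
  }, character(1))
}

#' Mendelian exclusion rules for diploid and triploid trios
#'
#' Enumerates, for every parent-genotype configuration (including one missing
#' parent), the offspring genotypes impossible under Mendelian inheritance.
#' Diploid offspring receive one gamete from each parent. Triploid offspring
#' from pressure-shock induced triploidy receive a sister-chromatid pair from
#' the mother -- two identical alleles, or one of each where a crossover
#' separated the locus from the centromere, so a heterozygous mother can
#' contribute AA, AB or BB while a homozygous mother contributes only her own
#' pair -- plus one paternal allele. With `sexed = TRUE` parent 1 is the
#' mother and the mother-specific rows apply; with `sexed = FALSE` only
#' configurations excluded under both parent orderings count.
#'
#' The rule set is generated by brute-force enumeration of parental
#' contributions, not transcribed, so it doubles as an oracle.
#'
#' @param ploidy Offspring ploidy, 2 or 3.
#' @param sexed For triploids, whether parent order is (mother, father).
#' @return Tibble with `p1`, `p2` (dosage or `NA`), `offspring` (excluded
#'   dosage), plus `p1_label`, `p2_label`, `offspring_label`.
#' @export
exclusion_table <- function(ploidy, sexed = ploidy == 3) {
  stopifnot(ploidy %in% c(2, 3))
  parent_codes <- c(NA_integer_, 0:2)
  rows <- list()
  for (p1 in parent_codes) {
    for (p2 in parent_codes) {
      if (is.na(p1) && is.na(p2)) next
      excl <- excluded_offspring(p1, p2, ploidy, sexed)
      for (o in excl) {
        rows[[length(rows) + 1L]] <- tibble::tibble(p1 = p1, p2 = p2, offspring = o)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p1_label <- geno_label(out$p1, 2)
  out$p2_label <- geno_label(out$p2, 2)
  out$offspring_label <- geno_label(out$offspring, ploidy)
  out
}

# offspring dosages possible for one known-or-missing parent pair
possible_offspring <- function(p1, p2, ploidy, sexed) {
  p1s <- if (is.na(p1)) 0:2 else p1
  p2s <- if (is.na(p2)) 0:2 else p2
  poss <- integer(0)
  for (a in p1s) {
    for (b in p2s) {
      if (ploidy == 2) {
        # one gamete from each diploid parent
        g1 <- unique(c(if (a >= 1) 1L else NULL, if (a <= 1) 0L else NULL))
        g2 <- unique(c(if (b >= 1) 1L else NULL, if (b <= 1) 0L else NULL))
        poss <- c(poss, as.vector(outer(g1, g2, "+")))
      } else {
        # mother (a) contributes a chromatid pair, father (b) one allele
        mat <- if (a == 1) c(0L, 1L, 2L) else a   # hom mother: only her pair
        pat <- unique(c(if (b >= 1) 1L else NULL, if (b <= 1) 0L else NULL))
        poss <- c(poss, as.vector(outer(mat, pat, "+")))
      }
    }
  }
  sort(unique(poss))
}

excluded_offspring <- function(p1, p2, ploidy, sexed) {
  all_o <- 0:ploidy
  if (ploidy == 2 || sexed) {
    return(setdiff(all_o, possible_offspring(p1, p2, ploidy, sexed)))
  }
  # unsexed triploid: excluded under both orderings only
  e1 <- setdiff(all_o, possible_offspring(p1, p2, 3, TRUE))
  e2 <- setdiff(all_o, possible_offspring(p2, p1, 3, TRUE))
  intersect(e1, e2)
}

#' Opposing-homozygote exclusion for an offspring--candidate duo
#'
#' The sex-agnostic exclusion used for parentage ranking: a candidate parent
#' homozygous for one allele cannot have an offspring carrying only the other
#' allele (candidate AA with all-B offspring, or BB with all-A offspring).
#'
#' @param offspring_dosage Offspring dosage `0..ploidy` (vectorized).
#' @param candidate_dosage Candidate parent dosage `0..2` (vectorized).
#' @param ploidy Offspring ploidy, 2 or 3.
#' @return Logical vector; `NA` where either genotype is missing.
#' @export
duo_exclusion <- function(offspring_dosage, candidate_dosage, ploidy) {
  (candidate_dosage == 2L & offspring_dosage == 0L) |
    (candidate_dosage == 0L & offspring_dosage == ploidy)
}

#' Trio exclusion check
#'
#' Tests whether an offspring genotype is Mendelian-impossible given one or
#' both parents, using the full rule set from [exclusion_table()].
#'
#' @param offspring_dosage,p1_dosage,p2_dosage Dosages (vectorized; parent
#'   `NA` = missing genotype, handled by the missing-parent rows).
#' @param ploidy Offspring ploidy.
#' @param sexed Triploid only: is p1 the mother?
#' @return Logical vector (`NA` when the offspring is missing).
#' @export
trio_exclusion <- function(offspring_dosage, p1_dosage, p2_dosage, ploidy,
                           sexed = ploidy == 3) {
  tab <- exclusion_lookup(ploidy, sexed)
  n <- max(length(offspring_dosage), length(p1_dosage), length(p2_dosage))
  o <- rep_len(as.integer(offspring_dosage), n)
  p1 <- rep_len(as.integer(p1_dosage), n)
  p2 <- rep_len(as.integer(p2_dosage), n)
  i1 <- ifelse(is.na(p1), 4L, p1 + 1L)
  i2 <- ifelse(is.na(p2), 4L, p2 + 1L)
  out <- tab[cbind(i1, i2, o + 1L)]
  out[is.na(o)] <- NA
  out[is.na(p1) & is.na(p2)] <- FALSE
  out
}

# 4 x 4 x (ploidy+1) lookup (parent index 4 = missing), cached per R session
exclusion_lookup <- local({
  cache <- list()
  function(ploidy, sexed) {
    key <- paste0(ploidy, sexed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    arr <- array(FALSE, dim = c(4, 4, ploidy + 1))
    codes <- c(0:2, NA_integer_)
    for (i in 1:4) {
      for (j in 1:4) {
        if (i == 4 && j == 4) next
        excl <- excluded_offspring(codes[i], codes[j], ploidy, sexed)
        arr[i, j, excl + 1L] <- TRUE
      }
    }
    cache[[key]] <<- arr
    arr
  }
})

#' Mother-specific exclusion for a triploid offspring--candidate duo
#'
#' A triploid offspring inherits two maternal alleles, so its genotype
#' constrains the mother more than the father: offspring AAB or AAA rule out
#' a BB mother, and ABB or BBB rule out an AA mother (the plain opposing
#' homozygote cases are contained in these). A true father can produce any of
#' these configurations, which is what separates the sexes.
#'
#' @param offspring_dosage Triploid dosage `0..3` (vectorized).
#' @param candidate_dosage Candidate mother dosage `0..2` (vectorized).
#' @return Logical vector; `NA` where either genotype is missing.
#' @export
mother_exclusion <- function(offspring_dosage, candidate_dosage) {
  (candidate_dosage == 2L & offspring_dosage <= 1L) |
    (candidate_dosage == 0L & offspring_dosage >= 2L)
}

#' Exclusion statistics for all offspring--candidate duos
#'
#' For every pair of offspring and candidate parent, counts the markers
#' called in both, the opposing-homozygote exclusions, and the
#' mother-specific exclusions, and forms the exclusion ratios
#' `er = n_exclusions / n_compared` and
#' `mother_er = n_mother_exclusions / n_compared`. Missing genotypes never
#' count as exclusions and never enter `n_compared`. Pairs with zero compared
#' markers are dropped with a warning.
#'
#' @param offspring Long genotype tibble (`marker_id`, `sample_id`, `dosage`)
#'   for the offspring, or a `genocall`.
#' @param candidates Same, for the diploid candidate parents.
#' @param ploidy Offspring ploidy (default 3).
#' @return Tibble with `offspring_id`, `candidate_id`, `n_compared`,
#'   `n_exclusions`, `er`, `n_mother_exclusions`, `mother_er` (the mother
#'   columns are `NA` for diploid offspring).
#' @export
duo_stats <- function(offspring, candidates, ploidy = 3) {
  og <- if (inherits(offspring, "genocall")) offspring$genotypes else offspring
  cg <- if (inherits(candidates, "genocall")) candidates$genotypes else candidates
  shared <- intersect(unique(og$marker_id), unique(cg$marker_id))
  om <- contrast_matrix(dplyr::filter(og, .data$marker_id %in% shared), "dosage")
  cm <- contrast_matrix(dplyr::filter(cg, .data$marker_id %in% shared), "dosage")
  cm <- cm[rownames(om), , drop = FALSE]
  o_called <- !is.na(om)
  c_called <- !is.na(cm)
  n_comp <- t(c_called + 0) %*% (o_called + 0)            # cand x off
  excl <- t((cm == 2 & !is.na(cm)) + 0) %*% ((om == 0 & !is.na(om)) + 0) +
    t((cm == 0 & !is.na(cm)) + 0) %*% ((om == ploidy & !is.na(om)) + 0)
  out <- tibble::tibble(
    offspring_id = rep(colnames(om), each = ncol(cm)),
    candidate_id = rep(colnames(cm), times = ncol(om)),
    n_compared = as.integer(n_comp),
    n_exclusions = as.integer(excl)
  )
  if (ploidy == 3) {
    mexcl <- t((cm == 2 & !is.na(cm)) + 0) %*% ((om <= 1 & !is.na(om)) + 0) +
      t((cm == 0 & !is.na(cm)) + 0) %*% ((om >= 2 & !is.na(om)) + 0)
    out$n_mother_exclusions <- as.integer(mexcl)
  } else {
    out$n_mother_exclusions <- NA_integer_
  }
  empty <- out$n_compared == 0
  if (any(empty)) {
    warning(sum(empty), " offspring-candidate pair(s) with no mutually called markers dropped")
    out <- out[!empty, ]
  }
  out$er <- out$n_exclusions / out$n_compared
  out$mother_er <- out$n_mother_exclusions / out$n_compared
  dplyr::relocate(out, "offspring_id", "candidate_id", "n_compared",
                  "n_exclusions", "er", "n_mother_exclusions", "mother_er")
}

#' Trio exclusion ratio
#'
#' ER over full trios: the number of markers whose (offspring, p1, p2)
#' configuration is a Mendelian exclusion, divided by markers where the
#' offspring and at least one parent are called.
#'
#' @param trios Tibble with columns `offspring`, `p1`, `p2` (dosages, one row
#'   per marker x trio; `NA` = no-call).
#' @param ploidy Offspring ploidy.
#' @param sexed Is `p1` the mother (triploid trios)?
#' @return One-row tibble with `n_compared`, `n_exclusions`, `er`.
#' @export
trio_er <- function(trios, ploidy, sexed = ploidy == 3) {
  informative <- !is.na(trios$offspring) & (!is.na(trios$p1) | !is.na(trios$p2))
  ex <- trio_exclusion(trios$offspring, trios$p1, trios$p2, ploidy, sexed)
  n_comp <- sum(informative)
  n_ex <- sum(ex & informative, na.rm = TRUE)
  tibble::tibble(n_compared = n_comp, n_exclusions = n_ex,
                 er = ifelse(n_comp > 0, n_ex / n_comp, NA_real_))
}

#' Assign candidate parents to offspring by exclusion ratio
#'
#' Every candidate with `er` strictly below the threshold is assumed a true
#' parent. More than two assignments flag a conflict (duplicated parental
#' samples or a ploidy mix-up). The tibble also reports, per offspring, the
#' third-lowest candidate ER -- the diagnostic used to place the threshold
#' below the closest-fitting non-parent.
#'
#' @param duo_stats Tibble from [duo_stats()].
#' @param er_threshold Assignment threshold on ER (default 0.002, strict `<`).
#' @return Tibble with one row per assigned duo (`offspring_id`,
#'   `candidate_id`, `er`, `mother_er`, `er_rank`) plus per-offspring
#'   `n_assigned`, `conflict`, and `third_er`.
#' @export
assign_parentage <- function(duo_stats, er_threshold = 0.002) {
  ranked <- dplyr::mutate(
    dplyr::group_by(duo_stats, .data$offspring_id),
    er_rank = rank(.data$er, ties.method = "first"),
    third_er = sort(.data$er)[pmin(3L, dplyr::n())],
    n_assigned = sum(.data$er < er_threshold)
  )
  out <- dplyr::ungroup(dplyr::filter(ranked, .data$er < er_threshold))
  out$conflict <- out$n_assigned > 2L
  dplyr::select(out, "offspring_id", "candidate_id", "er", "mother_er",
                "er_rank", "n_assigned", "conflict", "third_er")
}

#' Predict the sex of assigned parents
#'
#' Among parents already assigned by ER, a candidate whose mother-specific
#' exclusion ratio is strictly below the threshold is labelled the mother;
#' `mother_er` at or above the threshold labels the father. Two mothers or
#' two fathers for one offspring flag a conflict (a sign of duplicated
#' parents or failed triploidy).
#'
#' @param assignments Tibble from [assign_parentage()] (needs `mother_er`).
#' @param mother_er_threshold Default 0.02; `mother_er < threshold` = mother.
#' @return `assignments` with `sex` (`"mother"`/`"father"`) and
#'   `sex_conflict` columns.
#' @export
predict_parent_sex <- function(assignments, mother_er_threshold = 0.02) {
  out <- dplyr::mutate(assignments,
    sex = ifelse(.data$mother_er < mother_er_threshold, "mother", "father"))
  conf <- dplyr::summarise(
    dplyr::group_by(out, .data$offspring_id),
    sex_conflict = sum(.data$sex == "mother") > 1 | sum(.data$sex == "father") > 1,
    .groups = "drop")
  dplyr::left_join(out, conf, by = "offspring_id")
}

#' Detect duplicated or contaminated samples
#'
#' Flags sample pairs whose dosage vectors correlate above `r_threshold`
#' (Pearson, over mutually called markers). Pairs with fewer than two
#' mutually called markers are skipped.
#'
#' @param genotypes A `genocall` or long genotype tibble.
#' @param r_threshold Correlation threshold (default 0.99, strict `>`).
#' @return Tibble with `sample_1`, `sample_2`, `r`, `n_shared`.
#' @export
detect_duplicates <- function(genotypes, r_threshold = 0.99) {
  g <- if (inherits(genotypes, "genocall")) genotypes$genotypes else genotypes
  m <- contrast_matrix(g, "dosage")
  if (ncol(m) < 2) stop("need at least two samples")
  called <- !is.na(m)
  n_shared <- crossprod(called + 0)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r) & !is.na(r) & r > r_threshold & n_shared >= 2,
               arr.ind = TRUE)
  tibble::tibble(
    sample_1 = colnames(m)[idx[, 1]],
    sample_2 = colnames(m)[idx[, 2]],
    r = r[idx],
    n_shared = as.integer(n_shared[idx])
  )
}
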