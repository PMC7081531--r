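test_that("generated exclusion rules reproduce the published diploid table", {
  tab <- exclusion_table(2)
  for (rule in published_diploid_rules) {
    p1 <- rule[[1]]; p2 <- rule[[2]]; excl <- rule[[3]]
    got <- tab$offspring[
      (is.na(tab$p1) == is.na(p1)) & (is.na(tab$p1) | tab$p1 %in% p1) &
        (is.na(tab$p2) == is.na(p2)) & (is.na(tab$p2) | tab$p2 %in% p2)]
    expect_setequal(got, excl)
  }
  # and nothing beyond the 12 published configurations is excluded
  expect_equal(nrow(dplyr::distinct(tab, p1, p2)), 12)
})

test_that("generated exclusion rules reproduce the published triploid table", {
  tab <- exclusion_table(3, sexed = TRUE)
  for (rule in published_triploid_rules) {
    p1 <- rule[[1]]; p2 <- rule[[2]]; excl <- rule[[3]]
    got <- tab$offspring[
      (is.na(tab$p1) == is.na(p1)) & (is.na(tab$p1) | tab$p1 %in% p1) &
        (is.na(tab$p2) == is.na(p2)) & (is.na(tab$p2) | tab$p2 %in% p2)]
    expect_setequal(got, excl)
  }
  expect_equal(nrow(dplyr::distinct(tab, p1, p2)), 12)
})

test_that("rule tables agree with independent gamete/chromatid enumeration", {
  for (ploidy in c(2, 3)) {
    for (p1 in c(NA, 0:2)) {
      for (p2 in c(NA, 0:2)) {
        if (is.na(p1) && is.na(p2)) next
        for (o in 0:ploidy) {
          expect_equal(
            trio_exclusion(o, p1, p2, ploidy, sexed = ploidy == 3),
            o %in% oracle_excluded(p1, p2, ploidy),
            info = sprintf("ploidy %d, p1=%s p2=%s o=%d", ploidy, p1, p2, o))
        }
      }
    }
  }
})

test_that("unsexed triploid exclusions are the sex-symmetric subset", {
  for (p1 in 0:2) for (p2 in 0:2) for (o in 0:3) {
    both <- o %in% oracle_excluded(p1, p2, 3) && o %in% oracle_excluded(p2, p1, 3)
    expect_equal(trio_exclusion(o, p1, p2, 3, sexed = FALSE), both)
  }
  # e.g. M=AA, F=BB excludes ABB when sexed, but not unsexed (F=AA, M=BB allows it)
  expect_true(trio_exclusion(1, 2, 0, 3, sexed = TRUE))
  expect_false(trio_exclusion(1, 2, 0, 3, sexed = FALSE))
})

test_that("spec-level trio examples hold", {
  expect_true(trio_exclusion(0, 1, 2, 2))                 # AB x AA -> BB
  expect_true(trio_exclusion(1, 2, 1, 3, sexed = TRUE))   # M=AA F=AB -> ABB
  expect_false(trio_exclusion(2, 1, 2, 3, sexed = TRUE))  # M=AB F=AA -> AAB fine
})

test_that("duo exclusion is opposing homozygotes only", {
  expect_true(duo_exclusion(3, 0, 3))   # BB candidate, AAA offspring
  expect_true(duo_exclusion(0, 2, 3))
  expect_true(duo_exclusion(2, 0, 2))
  for (o in 0:3) expect_false(duo_exclusion(o, 1, 3))  # het never excluded
  expect_false(duo_exclusion(1, 2, 2))  # AA parent, AB diploid offspring
})

test_that("duo exclusion is invariant under global allele relabeling", {
  for (ploidy in c(2, 3)) {
    for (o in 0:ploidy) for (cand in 0:2) {
      expect_equal(duo_exclusion(o, cand, ploidy),
                   duo_exclusion(ploidy - o, 2 - cand, ploidy))
    }
  }
})

test_that("mother-specific exclusions form exactly the published 4-cell truth table", {
  # brute force over maternal chromatid-pair contributions
  expected <- matrix(FALSE, 4, 3, dimnames = list(0:3, 0:2))
  for (o in 0:3) for (m in 0:2) {
    possible <- c()
    genos <- list(c(0, 0), c(0, 1), c(1, 1))[[m + 1]]
    pairs <- list(2 * genos[1], sum(genos), 2 * genos[2])
    for (pr in pairs) for (f in 0:1) possible <- c(possible, pr + f)
    expected[o + 1, m + 1] <- !(o %in% possible)
  }
  for (o in 0:3) for (m in 0:2) {
    expect_equal(mother_exclusion(o, m), expected[o + 1, m + 1])
  }
  # the four true cells: AA mother with ABB/BBB, BB mother with AAA/AAB
  expect_equal(sum(expected), 4)
  expect_true(mother_exclusion(2, 0))
  expect_false(mother_exclusion(2, 2))
})

test_that("duo statistics count exclusions over mutually called markers", {
  off <- tibble::tibble(
    marker_id = sprintf("M%d", 1:6), sample_id = "O1",
    dosage = c(3L, 0L, 2L, NA, 1L, 3L))
  cand <- tibble::tibble(
    marker_id = rep(sprintf("M%d", 1:6), 2),
    sample_id = rep(c("C1", "C2"), each = 6),
    dosage = c(0L, 2L, 1L, 1L, 1L, NA,    # C1: excl at M1 (BB vs AAA), M2
               2L, 2L, 2L, 2L, 2L, 2L))   # C2: excl at M2 only
  ds <- duo_stats(off, cand, ploidy = 3)
  c1 <- ds[ds$candidate_id == "C1", ]
  expect_equal(c1$n_compared, 4L)   # M4 missing in offspring, M6 in candidate
  expect_equal(c1$n_exclusions, 2L)
  expect_equal(c1$er, 0.5)
  c2 <- ds[ds$candidate_id == "C2", ]
  expect_equal(c2$n_compared, 5L)
  expect_equal(c2$n_exclusions, 1L)
  # mother exclusions add the AA-candidate vs ABB cell at M5
  expect_equal(c2$n_mother_exclusions, 2L)  # M2 (BBB), M5 (ABB)
})

test_that("er arithmetic: 5 exclusions over 10000 compared markers is 5e-4", {
  off <- tibble::tibble(marker_id = sprintf("M%05d", 1:10000),
                        sample_id = "O", dosage = 3L)
  cand <- off
  cand$sample_id <- "C"
  cand$dosage <- c(rep(0L, 5), rep(2L, 9995))
  ds <- duo_stats(off, cand, ploidy = 3)
  expect_equal(ds$n_compared, 10000L)
  expect_equal(ds$n_exclusions, 5L)
  expect_equal(ds$er, 5e-4)
})

test_that("non-relative duo ER matches the enumerated expectation under HWE", {
  set.seed(41)
  n <- 10000
  maf <- runif(n, 0.1, 0.5)
  cand <- rbinom(n, 2, maf)
  # triploid offspring of two other random HWE parents
  mother <- cbind(rbinom(n, 1, maf), rbinom(n, 1, maf))
  mat_pair <- ifelse(runif(n) < 0.5, 2 * mother[, 1], mother[, 1] + mother[, 2])
  off <- mat_pair + rbinom(n, 1, maf)
  er_obs <- mean(duo_exclusion(off, cand, 3))
  # enumerate the per-marker exclusion probability exactly
  p_excl <- vapply(seq_len(n), function(i) {
    p <- maf[i]
    p_cand <- dbinom(0:2, 2, p)
    # offspring dosage distribution: maternal pair (half 2*h1, half h1+h2) + paternal
    p_off <- numeric(4)
    for (h1 in 0:1) for (h2 in 0:1) for (f in 0:1) {
      pr <- p^h1 * (1 - p)^(1 - h1) * p^h2 * (1 - p)^(1 - h2) *
        p^f * (1 - p)^(1 - f)
      p_off[2 * h1 + f + 1] <- p_off[2 * h1 + f + 1] + pr / 2
      p_off[h1 + h2 + f + 1] <- p_off[h1 + h2 + f + 1] + pr / 2
    }
    p_cand[1] * p_off[4] + p_cand[3] * p_off[1]
  }, numeric(1))
  expected <- mean(p_excl)
  se <- sqrt(sum(p_excl * (1 - p_excl))) / n
  expect_lt(abs(er_obs - expected), 3 * se)
})

test_that("pairs with no mutually called markers are dropped with a warning", {
  off <- tibble::tibble(marker_id = c("M1", "M2"), sample_id = "O",
                        dosage = c(NA_integer_, NA_integer_))
  cand <- tibble::tibble(marker_id = c("M1", "M2"), sample_id = "C",
                         dosage = c(1L, 2L))
  expect_warning(ds <- duo_stats(off, cand, 3), "dropped")
  expect_equal(nrow(ds), 0)
})

test_that("parentage assignment applies a strict ER threshold", {
  ds <- tibble::tibble(
    offspring_id = "O1",
    candidate_id = sprintf("C%d", 1:5),
    n_compared = 1000L, n_exclusions = 0L,
    er = c(0.0003, 0.0008, 0.004, 0.01, 0.002),
    n_mother_exclusions = 0L, mother_er = 0)
  asg <- assign_parentage(ds, er_threshold = 0.002)
  expect_setequal(asg$candidate_id, c("C1", "C2"))  # 0.002 exactly: excluded
  expect_false(any(asg$conflict))
  expect_equal(unique(asg$third_er), 0.002)

  ds$er <- c(0.0001, 0.0002, 0.0003, 0.01, 0.02)
  asg3 <- assign_parentage(ds, 0.002)
  expect_equal(nrow(asg3), 3)
  expect_true(all(asg3$conflict))
})

test_that("sex labels follow the mother.ER rule with '>= threshold' = father", {
  asg <- tibble::tibble(
    offspring_id = c("O1", "O1"),
    candidate_id = c("C1", "C2"),
    er = 0.0001, mother_er = c(0.01, 0.02))
  sexed <- predict_parent_sex(asg, mother_er_threshold = 0.02)
  expect_equal(sexed$sex, c("mother", "father"))  # 0.02 exactly -> father
  expect_false(any(sexed$sex_conflict))
  asg$mother_er <- c(0.01, 0.015)
  expect_true(all(predict_parent_sex(asg, 0.02)$sex_conflict))  # two mothers
})

test_that("duplicate samples are detected by genotype correlation > 0.99", {
  set.seed(43)
  n <- 5000
  maf <- runif(n, 0.1, 0.5)
  s1 <- rbinom(n, 3, maf)
  s2 <- rbinom(n, 3, maf)  # independent
  g <- tibble::tibble(
    marker_id = rep(sprintf("M%05d", 1:n), 3),
    sample_id = rep(c("S1", "S2", "S1copy"), each = n),
    dosage = as.integer(c(s1, s2, s1)))
  dup <- detect_duplicates(g, 0.99)
  expect_equal(nrow(dup), 1)
  expect_setequal(unlist(dup[, 1:2]), c("S1", "S1copy"))
  expect_equal(dup$r, 1)
})

test_that("trio ER falls to zero as the genotype error rate vanishes", {
  set.seed(44)
  ers <- vapply(c(0.05, 0.01, 0), function(eps) {
    cfg <- sim_config(n_markers = 150, n_mothers = 2, n_fathers = 2,
                      offspring_per_cross = 5, genotype_error_rate = eps,
                      seed = 97)
    sim <- simulate_dataset(cfg)
    # corrupt truth dosages the same way the signal stage would
    obs <- sim$offspring_dosage
    err <- sim$signal_errors$offspring
    shift <- 1L + floor(runif(sum(err)) * 3)
    obs[err] <- (obs[err] + shift) %% 4L
    trios <- build_trios(
      tibble::tibble(marker_id = rep(rownames(obs), ncol(obs)),
                     sample_id = rep(colnames(obs), each = nrow(obs)),
                     dosage = as.integer(obs)),
      sim_truth_genotypes(sim, "parents"), sim$pedigree)
    trio_er(dplyr::rename(trios, p1 = mother, p2 = father), 3, sexed = TRUE)$er
  }, numeric(1))
  expect_true(all(diff(ers) <= 0))
  expect_equal(ers[3], 0)
})
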