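# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force observed-data log-likelihood of a univariate normal mixture.
oracle_loglik <- function(x, weights, means, variances) {
  total <- 0
  for (xi in x) {
    s <- 0
    for (k in seq_along(weights)) {
      s <- s + weights[k] * exp(-(xi - means[k])^2 / (2 * variances[k])) /
        sqrt(2 * pi * variances[k])
    }
    total <- total + log(s)
  }
  total
}

# Brute-force enumeration of possible offspring dosages from explicit allele
# lists (1 = A, 0 = B). Missing parent = any diploid genotype.
oracle_possible_diploid <- function(p1, p2) {
  genos <- list(c(0, 0), c(0, 1), c(1, 1))
  g1 <- if (is.na(p1)) genos else genos[p1 + 1]
  g2 <- if (is.na(p2)) genos else genos[p2 + 1]
  poss <- c()
  for (a in g1) for (b in g2) {
    for (i in 1:2) for (j in 1:2) poss <- c(poss, a[i] + b[j])
  }
  sort(unique(poss))
}

# Triploid: mother transmits a chromatid pair (two copies of one of her
# alleles, or -- if a crossover separated locus and centromere -- one of
# each); father transmits a single allele.
oracle_possible_triploid <- function(mother, father) {
  genos <- list(c(0, 0), c(0, 1), c(1, 1))
  gm <- if (is.na(mother)) genos else genos[mother + 1]
  gf <- if (is.na(father)) genos else genos[father + 1]
  poss <- c()
  for (m in gm) {
    pairs <- list(c(m[1], m[1]), c(m[1], m[2]), c(m[2], m[2]))
    for (f in gf) for (pr in pairs) for (j in 1:2) {
      poss <- c(poss, sum(pr) + f[j])
    }
  }
  sort(unique(poss))
}

oracle_excluded <- function(p1, p2, ploidy) {
  poss <- if (ploidy == 2) oracle_possible_diploid(p1, p2) else
    oracle_possible_triploid(p1, p2)
  setdiff(0:ploidy, poss)
}

# The published exclusion rule sets, frozen as (p1, p2, excluded dosages).
# Diploid: parents symmetric; triploid: p1 is the mother.
published_diploid_rules <- list(
  list(NA, 2, 0), list(NA, 0, 2), list(2, NA, 0), list(0, NA, 2),
  list(2, 0, c(0, 2)), list(0, 2, c(0, 2)),
  list(2, 2, c(0, 1)), list(0, 0, c(1, 2)),
  list(1, 2, 0), list(1, 0, 2), list(2, 1, 0), list(0, 1, 2)
)
published_triploid_rules <- list(
  list(0, NA, c(2, 3)), list(2, NA, c(0, 1)),
  list(NA, 2, 0), list(NA, 0, 3),
  list(2, 0, c(0, 1, 3)), list(0, 2, c(0, 2, 3)),
  list(2, 2, c(0, 1, 2)), list(0, 0, c(1, 2, 3)),
  list(2, 1, c(0, 1)), list(0, 1, c(2, 3)),
  list(1, 2, 0), list(1, 0, 3)
)

# Tiny deterministic signal fixture writers (text fixtures built in code).
write_axiom_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}
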