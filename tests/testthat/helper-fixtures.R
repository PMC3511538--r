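# Shared fixtures: tiny case collections, random-instance generators, and
# the brute-force itemset oracle used to validate the level-wise search.

# four cases of one disorder; S1 = Short stature (4/4), S2 = Cleft palate (2/4)
achondroplasia_collection <- function() {
  encode_cases(data.frame(
    case_id = c("p1", "p2", "p3", "p4"),
    diagnosis = "Achondroplasia",
    phenotypes = c("Short stature|Cleft palate", "Short stature",
                   "Short stature|Cleft palate", "Short stature"),
    stringsAsFactors = FALSE))
}

# random case collection over at most n_symbols phenotype terms and
# n_disorders diagnoses; phenotype count per case 1..4
random_collection <- function(n_symbols = 10L, n_cases = 30L,
                              n_disorders = 3L, seed = 1L) {
  set.seed(seed)
  terms <- sprintf("pheno%02d", seq_len(n_symbols))
  dis <- sprintf("disorder%02d", seq_len(n_disorders))
  raw <- lapply(seq_len(n_cases), function(i) {
    list(case_id = sprintf("c%03d", i),
         diagnosis = sample(dis, 1L),
         phenotypes = sample(terms, sample.int(min(4L, n_symbols), 1L)))
  })
  encode_cases(raw)
}

# exhaustive power-set support counting; the independent oracle for
# find_frequent_itemsets on small instances
brute_force_itemsets <- function(collection, min_support_count = 2L,
                                 max_size = 10L) {
  txns <- lapply(collection$cases, function(cs) {
    t <- cs$phenotypes
    if (!is.na(cs$diagnosis)) t <- c(t, cs$diagnosis)
    unique(t)
  })
  universe <- sort(unique(unlist(txns)))
  M <- vapply(universe, function(u) {
    vapply(txns, function(t) u %in% t, TRUE)
  }, logical(length(txns)))
  M <- matrix(M, nrow = length(txns))
  out <- list()
  for (k in seq_len(min(max_size, length(universe)))) {
    sets <- utils::combn(seq_along(universe), k, simplify = FALSE)
    for (s in sets) {
      supp <- sum(rowSums(M[, s, drop = FALSE]) == k)
      if (supp >= min_support_count) {
        out[[length(out) + 1L]] <- list(items = universe[s],
                                        support_count = supp)
      }
    }
  }
  out
}

# canonical "key=support" multiset for itemset comparison
canon_itemsets <- function(itemsets) {
  sort(vapply(itemsets, function(s) {
    paste0(paste(sort(s$items), collapse = ","), "=", s$support_count)
  }, ""))
}

# a random simple support function over a small symbol pool
random_simple_mass <- function() {
  n_ph <- sample.int(3L, 1L)
  rule <- list(antecedent = sort(sample(paste0("S", 1:5), n_ph)),
               consequent = sample(paste0("D", 1:3), 1L),
               confidence = runif(1L, 0.05, 0.95))
  rule_to_mass(rule)
}

expect_mass_valid <- function(m, tol = 1e-9) {
  expect_s3_class(m, "mass_function")
  expect_true(all(m$focal >= -tol))
  expect_gte(m$theta, -tol)
  expect_lt(abs(sum(m$focal) + m$theta - 1), tol)
}

# compare two mass functions focal-by-focal
expect_mass_equal <- function(m1, m2, tol = 1e-9) {
  keys <- union(names(m1$focal), names(m2$focal))
  for (k in keys) {
    v1 <- if (k %in% names(m1$focal)) m1$focal[[k]] else 0
    v2 <- if (k %in% names(m2$focal)) m2$focal[[k]] else 0
    expect_lt(abs(v1 - v2), tol)
  }
  expect_lt(abs(m1$theta - m2$theta), tol)
}

# config of the scaled six-class experiment: class sizes of the published
# well-represented disorders, sparseness tuned to ~11% mean coverage
sixclass_config <- function(seed) {
  synthetic_config(seed = seed, n_disorders = 6L,
                   class_sizes = c(22L, 75L, 33L, 28L, 101L, 24L),
                   feature_weight_shape = 0.5,
                   noise_feature_rate = 0.12)
}
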