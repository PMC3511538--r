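test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(n_disorders = 20L, seed = 9)
  a <- generate_cases(cfg)
  b <- generate_cases(cfg)
  expect_identical(a$cases, b$cases)
  c2 <- generate_cases(synthetic_config(n_disorders = 20L, seed = 10))
  expect_false(identical(a$cases, c2$cases))
})

test_that("generated collections satisfy the case-collection invariants", {
  cc <- generate_cases(synthetic_config(n_disorders = 25L, seed = 4))
  expect_identical(cc$N, length(cc$cases))
  for (cs in cc$cases) {
    expect_gte(length(cs$phenotypes), 1L)
    expect_lte(length(cs$phenotypes), 20L)
    expect_false(anyNA(decode_symbol(cc$dictionary, cs$phenotypes)))
    expect_false(is.na(cs$diagnosis))
    expect_true(all(startsWith(cs$phenotypes, "S")))
  }
})

test_that("without noise every case stays inside its disorder's signature", {
  cfg <- synthetic_config(n_disorders = 10L, noise_feature_rate = 0,
                          seed = 6)
  cc <- generate_cases(cfg)
  sig <- attr(cc, "signatures")
  for (cs in cc$cases) {
    dterm <- decode_symbol(cc$dictionary, cs$diagnosis)
    feats <- decode_symbol(cc$dictionary, cs$phenotypes)
    expect_true(all(feats %in% sig[[dterm]]))
  }
})

test_that("class sizes follow the configured bin weights", {
  cc <- generate_cases(synthetic_config(n_disorders = 200L, seed = 12))
  diag <- vapply(cc$cases, `[[`, "", "diagnosis")
  sizes <- as.numeric(table(diag))
  # rare-disorder signature: most classes small, a few large
  expect_gt(mean(sizes <= 5), 0.55)           # ~70% configured, binomial slack
  expect_lt(mean(sizes > 50), 0.10)           # ~4% configured
  expect_gt(max(sizes), 20)
})

test_that("the default sparseness lands near the target mean coverage", {
  covs <- vapply(c(101, 102, 103), function(s) {
    cc <- generate_cases(synthetic_config(seed = s, n_disorders = 160L))
    expect_gte(cc$N, 1000L)
    coverage_summary(cc)$mean
  }, 0)
  for (v in covs) expect_lt(abs(v - 11.33), 3)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(vocabulary_size = 100L),
               "vocabulary smaller")
  expect_error(synthetic_config(noise_feature_rate = 1.5), "noise_feature_rate")
  expect_error(generate_cases(synthetic_config(class_sizes = c(2L, 3L))),
               "class_sizes length")
})

test_that("planted collections carry their ground truth and are separable", {
  pl <- generate_planted(n_classes = 3, cases_per_class = 10,
                         signature_size = 4, seed = 1)
  cc <- pl$collection
  expect_identical(cc$N, 30L)
  # every case carries its full class signature
  diag <- vapply(cc$cases, `[[`, "", "diagnosis")
  for (d in unique(diag)) {
    phenos <- lapply(cc$cases[diag == d], `[[`, "phenotypes")
    expect_length(unique(phenos), 1L)
    expect_length(phenos[[1]], 4L)
  }
  # ground-truth rules: every non-empty signature subset, confidence 1
  expect_length(pl$rules, 3 * (2^4 - 1))
  expect_true(all(vapply(unclass(pl$rules), `[[`, 0, "confidence") == 1))
})

test_that("mining recovers every planted rule at confidence 1", {
  pl <- generate_planted(n_classes = 3, cases_per_class = 10,
                         signature_size = 4, seed = 3)
  mined <- derive_rules(find_frequent_itemsets(pl$collection,
                                               min_support_count = 2))
  key <- function(r) paste(paste(r$antecedent, collapse = ","), r$consequent,
                           sep = "->")
  mined_keys <- vapply(unclass(mined), key, "")
  mined_conf <- vapply(unclass(mined), `[[`, 0, "confidence")
  for (r in unclass(pl$rules)) {
    i <- match(key(r), mined_keys)
    expect_false(is.na(i))
    expect_identical(mined_conf[[i]], 1)
  }
})

test_that("ranking a full signature puts its class first with near-certain belief", {
  pl <- generate_planted(n_classes = 3, cases_per_class = 10,
                         signature_size = 4, seed = 8)
  fit <- evidence_model(pl$collection)
  diag <- vapply(pl$collection$cases, `[[`, "", "diagnosis")
  for (d in unique(diag)) {
    q <- pl$collection$cases[[match(d, diag)]]$phenotypes
    r <- rank_candidates(q, fit$rules)
    expect_identical(r$entries$disorder[[1]], d)
    expect_gt(r$entries$belief[[1]], 1 - 1e-9)
  }
})

test_that("the statistics report reflects the generated collection", {
  cc <- generate_cases(synthetic_config(n_disorders = 30L, seed = 2))
  rep <- synthetic_report(cc)
  get <- function(k) rep$value[rep$statistic == k]
  expect_identical(get("n_cases"), as.numeric(cc$N))
  expect_identical(get("n_classes"), 30)
  expect_lte(get("features_per_case_max"), 20)
  expect_gte(get("features_per_case_mean"), 1)
})
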