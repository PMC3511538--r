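test_that("a uniform corpus yields the full lattice of its single transaction", {
  cc <- encode_cases(lapply(1:3, function(i) {
    list(case_id = paste0("c", i), diagnosis = "dx", phenotypes = "a")
  }))
  fi <- find_frequent_itemsets(cc, min_support_count = 2)
  expect_identical(canon_itemsets(fi),
                   sort(c("S1=3", "D1=3", "D1,S1=3")))
})

test_that("itemsets below minimum support are pruned", {
  cc <- encode_cases(list(
    list(case_id = "c1", diagnosis = "dx", phenotypes = c("a", "b")),
    list(case_id = "c2", diagnosis = "dx", phenotypes = "a"),
    list(case_id = "c3", diagnosis = "dx", phenotypes = "b")))
  fi <- find_frequent_itemsets(cc, min_support_count = 2)
  keys <- canon_itemsets(fi)
  expect_false(any(grepl("^S1,S2=", keys) | grepl("=1$", keys)))
  expect_true("S1=2" %in% keys && "S2=2" %in% keys)
})

test_that("level-wise search equals brute-force enumeration on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    cc <- random_collection(n_symbols = sample(5:10, 1),
                            n_cases = sample(10:30, 1),
                            n_disorders = sample(2:3, 1),
                            seed = seed)
    ms <- sample(2:3, 1)
    got <- canon_itemsets(find_frequent_itemsets(cc, min_support_count = ms))
    want <- canon_itemsets(brute_force_itemsets(cc, min_support_count = ms))
    expect_identical(got, want)
  }
})

test_that("max_size truncates the search and support is monotone", {
  cc <- random_collection(n_symbols = 6, n_cases = 20, seed = 42)
  fi <- find_frequent_itemsets(cc, min_support_count = 2, max_size = 2)
  expect_true(all(vapply(unclass(fi), function(s) length(s$items), 0L) <= 2))

  fi_all <- find_frequent_itemsets(cc, min_support_count = 2)
  supp <- new.env(parent = emptyenv())
  for (s in unclass(fi_all)) {
    assign(paste(sort(s$items), collapse = ","), s$support_count, envir = supp)
  }
  for (s in unclass(fi_all)) {
    if (length(s$items) < 2) next
    for (drop in seq_along(s$items)) {
      sub <- paste(sort(s$items[-drop]), collapse = ",")
      expect_gte(get(sub, envir = supp), s$support_count)
    }
  }
})

test_that("rule count never increases with the support threshold", {
  cc <- random_collection(n_symbols = 8, n_cases = 30, seed = 5)
  n_rules <- vapply(2:5, function(ms) {
    length(derive_rules(find_frequent_itemsets(cc, min_support_count = ms)))
  }, 0L)
  expect_true(all(diff(n_rules) <= 0))
})

test_that("rules partition an itemset into phenotype antecedent and disorder consequent", {
  cc <- encode_cases(lapply(1:2, function(i) {
    list(case_id = paste0("c", i), diagnosis = "Achondroplasia",
         phenotypes = "Dwarfism")
  }))
  rules <- derive_rules(find_frequent_itemsets(cc))
  expect_length(rules, 1L)
  r <- rules[[1]]
  expect_identical(decode_symbol(cc$dictionary, r$antecedent), "Dwarfism")
  expect_identical(decode_symbol(cc$dictionary, r$consequent), "Achondroplasia")
  expect_identical(r$confidence, 1)
})

test_that("confidence is the exact support ratio and needs no threshold", {
  # S1 in 4 cases; {S1, D1} in 3 of them -> confidence 0.75
  cc <- encode_cases(list(
    list(case_id = "c1", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c2", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c3", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c4", diagnosis = "dx2", phenotypes = "a")))
  rules <- derive_rules(find_frequent_itemsets(cc))
  df <- as.data.frame(rules)
  expect_identical(df$confidence[df$consequent == "D1"], 0.75)
  # the low-confidence complement rule is retained (no confidence filter)
  expect_false("D2" %in% df$consequent)  # {S1,D2} has support 1 < 2
  cc5 <- encode_cases(list(
    list(case_id = "c1", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c2", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c3", diagnosis = "dx1", phenotypes = "a"),
    list(case_id = "c4", diagnosis = "dx2", phenotypes = "a"),
    list(case_id = "c5", diagnosis = "dx2", phenotypes = "a")))
  df5 <- as.data.frame(derive_rules(find_frequent_itemsets(cc5)))
  expect_identical(sort(df5$confidence), c(0.4, 0.6))
})

test_that("itemsets without a disorder or without phenotypes yield no rule", {
  cc <- encode_cases(list(
    list(case_id = "c1", diagnosis = NA, phenotypes = c("a", "b")),
    list(case_id = "c2", diagnosis = NA, phenotypes = c("a", "b"))))
  fi <- find_frequent_itemsets(cc)
  expect_gt(length(fi), 0L)
  expect_length(derive_rules(fi), 0L)
})

test_that("a missing antecedent in the frequent set is an internal error", {
  broken <- structure(list(list(items = c("S1", "D1"), support_count = 2L)),
                      class = "frequent_itemsets")
  expect_error(derive_rules(broken), "downward closure")
})
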