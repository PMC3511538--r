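test_that("a rule becomes a simple support function", {
  m <- rule_to_mass(list(antecedent = "S1", consequent = "D1",
                         confidence = 0.75))
  expect_identical(unname(m$focal[[make_focal_key(c("S1", "D1"))]]), 0.75)
  expect_identical(m$theta, 0.25)
  expect_mass_valid(m)

  m1 <- rule_to_mass(list(antecedent = "S1", consequent = "D1",
                          confidence = 1))
  expect_identical(m1$theta, 0)

  expect_error(rule_to_mass(list(antecedent = "S1", consequent = "D1",
                                 confidence = 0)), "confidence")
  expect_error(rule_to_mass(list(antecedent = "S1", consequent = "D1",
                                 confidence = 1.2)), "confidence")
})

test_that("mass functions enforce the basic belief axioms", {
  expect_error(mass_function(stats::setNames(0.5, ""), 0.5), "empty set")
  expect_error(mass_function(stats::setNames(0.5, "S1"), 0.2), "sum to 1")
  expect_error(mass_function(stats::setNames(-0.1, "S1"), 1.1), "non-negative")
})

test_that("the vacuous mass is the identity of Dempster's rule", {
  set.seed(1)
  for (i in 1:10) {
    m <- random_simple_mass()
    expect_mass_equal(combine(m, vacuous_mass()), m, tol = 1e-15)
    expect_mass_equal(combine(vacuous_mass(), m), m, tol = 1e-15)
  }
})

test_that("combination reproduces the hand-enumerated joint mass", {
  # two conflicting conclusions sharing a phenotype: four product terms,
  # no empty intersection, K = 0
  m1 <- rule_to_mass(list(antecedent = "S1", consequent = "D1",
                          confidence = 0.6))
  m2 <- rule_to_mass(list(antecedent = "S1", consequent = "D2",
                          confidence = 0.5))
  j <- combine(m1, m2)
  expect_equal(attr(j, "conflict"), 0)
  expect_equal(unname(j$focal[[make_focal_key(c("S1", "D1"))]]), 0.30)
  expect_equal(unname(j$focal[[make_focal_key(c("S1", "D2"))]]), 0.20)
  expect_equal(unname(j$focal[[make_focal_key("S1")]]), 0.30)
  expect_equal(j$theta, 0.20)
  expect_mass_valid(j)
})

test_that("conflicting masses renormalize by 1 - K", {
  # m1({D1}) = 0.8, m2({D2}) = 0.5: K = 0.4, survivors scaled by 1/0.6
  m1 <- mass_function(stats::setNames(0.8, make_focal_key("D1")), 0.2)
  m2 <- mass_function(stats::setNames(0.5, make_focal_key("D2")), 0.5)
  j <- combine(m1, m2)
  expect_equal(attr(j, "conflict"), 0.4)
  expect_equal(unname(j$focal[[make_focal_key("D1")]]), 0.4 / 0.6)
  expect_equal(unname(j$focal[[make_focal_key("D2")]]), 0.1 / 0.6)
  expect_equal(j$theta, 0.1 / 0.6)
  expect_mass_valid(j)
})

test_that("total conflict raises an explicit error, never NaN", {
  m1 <- mass_function(stats::setNames(1, make_focal_key("D1")), 0)
  m2 <- mass_function(stats::setNames(1, make_focal_key("D2")), 0)
  expect_error(combine(m1, m2), class = "beliefmine_total_conflict")
  err <- tryCatch(combine_all(list(m1, vacuous_mass(), m2)),
                  beliefmine_total_conflict = function(e) e)
  expect_s3_class(err, "beliefmine_total_conflict")
  expect_match(conditionMessage(err), "3")  # names the offending evidence
})

test_that("combination is commutative and order-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    masses <- replicate(sample(3:5, 1), random_simple_mass(),
                        simplify = FALSE)
    ref <- combine_all(masses)
    expect_mass_valid(ref)
    perm <- sample(seq_along(masses))
    expect_mass_equal(combine_all(masses[perm]), ref, tol = 1e-9)
    expect_mass_equal(combine(masses[[1]], masses[[2]]),
                      combine(masses[[2]], masses[[1]]), tol = 1e-12)
  }
})

test_that("a single mass and all-vacuous lists pass through combine_all", {
  m <- random_simple_mass()
  expect_identical(combine_all(list(m))$focal, m$focal)
  v <- combine_all(replicate(4, vacuous_mass(), simplify = FALSE))
  expect_length(v$focal, 0L)
  expect_equal(v$theta, 1)
})

test_that("constrained belief sums exactly the qualifying focal sets", {
  m <- rule_to_mass(list(antecedent = "S1", consequent = "D1",
                         confidence = 0.75))
  expect_identical(constrained_belief(m, c("S1", "S2"), "D1"), 0.75)
  expect_identical(constrained_belief(m, c("S1", "S2"), "D2"), 0)
  # focal set not contained in A contributes nothing to belief
  expect_identical(constrained_belief(m, "S2", "D1"), 0)

  m1 <- rule_to_mass(list(antecedent = "S1", consequent = "D1",
                          confidence = 0.6))
  m2 <- rule_to_mass(list(antecedent = "S1", consequent = "D2",
                          confidence = 0.5))
  j <- combine(m1, m2)
  expect_equal(constrained_belief(j, "S1", "D1"), 0.30)
  expect_equal(constrained_belief(j, "S1", "D2"), 0.20)
})

test_that("plausibility dominates belief everywhere", {
  set.seed(9)
  for (rep in 1:20) {
    masses <- replicate(sample(2:4, 1), random_simple_mass(),
                        simplify = FALSE)
    j <- combine_all(masses)
    A <- sample(paste0("S", 1:5), sample.int(4, 1))
    for (d in paste0("D", 1:3)) {
      bel <- constrained_belief(j, A, d)
      pl <- constrained_plausibility(j, A, d)
      expect_gte(pl, bel - 1e-12)
      expect_gte(bel, 0)
      expect_lte(pl, 1)
    }
  }
})

test_that("belief arguments are validated", {
  m <- random_simple_mass()
  expect_error(constrained_belief(m, character(0), "D1"), "non-empty")
  expect_error(constrained_belief(m, "S1", "S2"), "disorder symbol")
  expect_error(constrained_plausibility(m, "S1", "S2"), "disorder symbol")
})
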