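# Majority vote, mass construction, Dempster's rule, pignistic decisions,
# Bayesian fusion.

test_that("majority vote follows the multiset and the documented tie rule", {
  expect_equal(majority_vote(c("PD", "PD", "Healthy", "PD")), "PD")
  expect_equal(majority_vote(c("PD", "PD", "Healthy", "Healthy"),
                             scores = c(Healthy = 0.64, PD = 0.71)), "PD")
  expect_equal(majority_vote(c("Healthy", "PD"),
                             scores = c(Healthy = 0.8, PD = 0.2)), "Healthy")
  # permutation invariance
  set.seed(2)
  for (rep in 1:10) {
    v <- sample(c("PD", "Healthy"), 5, replace = TRUE)
    expect_equal(majority_vote(v), majority_vote(sample(v)))
  }
  expect_warning(tied <- majority_vote(c("PD", "Healthy")), "tie")
  expect_equal(tied, "Healthy")
})

test_that("mass construction encodes reliability as simple support", {
  m <- build_mass("PD", 1)
  expect_equal(unname(m[["PD"]]), 1)
  m <- build_mass("Healthy", 0.5)
  expect_equal(unname(m[["Healthy"]]), 0.5)
  expect_equal(unname(m[["Theta"]]), 0.5)
  expect_error(build_mass("PD", NULL), "reliability")
})

test_that("smoothed reliability matches the hand-computed confusion example", {
  # confusion (Tp, Tn, Fp, Fn) = (9, 8, 1, 2), positive class PD
  truth <- c(rep("PD", 11), rep("Healthy", 9))
  pred <- c(rep("PD", 9), rep("Healthy", 2), rep("Healthy", 8), "PD")
  rel <- estimate_reliability(truth, pred)
  expect_equal(rel$PD, (9 + 1) / (10 + 2), tolerance = 1e-9)  # 0.8333
  expect_equal(rel$Healthy, (8 + 1) / (10 + 2), tolerance = 1e-9)
  lk <- estimate_likelihood(truth, pred)
  expect_equal(lk["PD", "PD"], (9 + 1) / (11 + 2))
  expect_equal(unname(rowSums(lk)), c(1, 1), tolerance = 1e-9)
})

test_that("Dempster's rule matches the worked example and the brute-force oracle", {
  m1 <- mass_function(healthy = 0.8, theta = 0.2)
  m2 <- mass_function(pd = 0.6, theta = 0.4)
  m <- dempster_combine(m1, m2)
  # K = 0.48; surviving masses 0.32, 0.12, 0.08 renormalised by 0.52
  expect_equal(unname(unclass(m)), c(8, 3, 2) / 13, tolerance = 1e-9)
  expect_lt(max(abs(unclass(m) - c(0.6154, 0.2308, 0.1538))), 1e-4)

  # vacuous identity
  vac <- mass_function()
  expect_equal(unclass(dempster_combine(m1, vac)), unclass(m1),
               tolerance = 1e-12)

  # total conflict
  expect_error(dempster_combine(mass_function(healthy = 1),
                                mass_function(pd = 1)),
               class = "copemd_conflict")

  # random masses, n in 2..4: agreement with 3^n focal enumeration,
  # commutativity and associativity to 1e-12
  set.seed(6)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    masses <- lapply(seq_len(n), function(i) {
      w <- runif(3); w <- w / sum(w)
      mass_function(w[1], w[2], w[3])
    })
    ours <- unclass(Reduce(dempster_combine, masses))
    oracle <- brute_dempster(masses)
    expect_equal(ours, oracle, tolerance = 1e-10)
    ours_rev <- unclass(Reduce(dempster_combine, rev(masses)))
    expect_equal(ours, ours_rev, tolerance = 1e-12)
    if (n >= 3) {
      regrouped <- dempster_combine(
        masses[[1]], Reduce(dempster_combine, masses[-1]))
      expect_equal(ours, unclass(regrouped), tolerance = 1e-12)
    }
  }
})

test_that("DS decisions follow pignistic probability and fall back on conflict", {
  four <- replicate(4, build_mass("PD", 0.9), simplify = FALSE)
  combined <- Reduce(dempster_combine, four)
  expect_gt(pignistic(combined)[["PD"]], 0.99)
  expect_equal(ds_decide(four), "PD")

  # a single informative source wins over vacuous companions
  expect_equal(ds_decide(list(mass_function(), mass_function(),
                              mass_function(healthy = 0.7, theta = 0.3))),
               "Healthy")

  # order invariance
  mix <- list(build_mass("PD", 0.8), build_mass("Healthy", 0.6),
              build_mass("PD", 0.55), build_mass("Healthy", 0.7))
  expect_equal(ds_decide(mix), ds_decide(rev(mix)))

  # total conflict: error without fallback, majority vote with it
  conflicted <- list(mass_function(healthy = 1), mass_function(pd = 1))
  expect_error(ds_decide(conflicted), class = "copemd_conflict")
  expect_warning(
    out <- ds_decide(conflicted,
                     fallback_decisions = c("Healthy", "PD", "PD"),
                     fallback_scores = c(Healthy = 0.4, PD = 0.6)),
    "majority")
  expect_equal(out, "PD")
})

test_that("Bayesian fusion matches two-term computations and ignores noise", {
  # single classifier: posterior(PD) = 0.9 / (0.9 + 0.2)
  lk <- matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE,
               dimnames = list(c("Healthy", "PD"), c("Healthy", "PD")))
  priors <- c(Healthy = 0.5, PD = 0.5)
  expect_equal(bayes_fuse("PD", list(lk), priors), "PD")
  # posterior check by direct computation
  post_pd <- 0.5 * 0.9 / (0.5 * 0.9 + 0.5 * 0.2)
  expect_equal(post_pd, 0.8182, tolerance = 1e-4)

  # unanimous decisions with diagonal confusions win outright
  diag_lk <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE,
                    dimnames = dimnames(lk))
  expect_equal(bayes_fuse(c("Healthy", "Healthy", "Healthy"),
                          rep(list(diag_lk), 3), priors), "Healthy")

  # an uninformative classifier never changes the decision
  flat <- matrix(0.5, 2, 2, dimnames = dimnames(lk))
  base <- bayes_fuse(c("PD", "Healthy"), list(lk, lk), priors)
  with_flat <- bayes_fuse(c("PD", "Healthy", "PD"), list(lk, lk, flat), priors)
  expect_equal(base, with_flat)

  # Bayes and DS coincide on unanimous inputs
  rels <- list(Healthy = 0.85, PD = 0.9)
  masses <- replicate(4, build_mass("PD", rels$PD), simplify = FALSE)
  expect_equal(ds_decide(masses),
               bayes_fuse(rep("PD", 4), rep(list(diag_lk), 4), priors))
})
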