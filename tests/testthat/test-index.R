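test_that("EBV standardization uses the population-SD convention", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(50, ap, seed = 21)
  pop <- simulate_ebv(pop, ap)
  z <- standardize_ebv(pop)
  expect_equal(colMeans(z), c(A = 0, B = 0), tolerance = 1e-10)
  expect_equal(sqrt(colMeans(z^2)), c(A = 1, B = 1), tolerance = 1e-10)
  # location invariance
  shifted <- pop
  shifted$ebv <- pop$ebv + 7
  expect_equal(standardize_ebv(shifted), z)
  # two animals with EBVs {1, 3} standardize to {-1, +1}
  two <- pop
  two$ebv <- matrix(c(1, 3, 1, 3), 2, dimnames = list(NULL, c("A", "B")))
  two$id <- 1:2
  expect_equal(unname(standardize_ebv(two)[, "A"]), c(-1, 1))
  const <- pop
  const$ebv[, "A"] <- 5
  expect_error(standardize_ebv(const), "zero EBV variance")
})

test_that("trait merits encode the selection goals", {
  expect_equal(trait_merit(1.0, "increase"), 1.0)
  expect_equal(trait_merit(c(-2, 0.5), "decrease"), c(2, -0.5))
  # stabilizing merit peaks (at zero) on the target
  expect_equal(trait_merit(-0.5, "stabilize", target_z = -0.5), 0)
  expect_equal(trait_merit(1.0, "stabilize", target_z = -0.5), -1.5)
  expect_lt(trait_merit(0.2, "stabilize", target_z = 0),
            trait_merit(0, "stabilize", target_z = 0))
  expect_equal(trait_merit(0.3, "resilience-actual"), 0.3)
  expect_equal(trait_merit(0.3, "resilience-absolute"), -0.3)
  expect_error(trait_merit(0, "stabilize"), "target_z")
  expect_error(trait_merit(0, "increase", target_z = 1), "target_z")
  expect_error(trait_merit(0, "maximize"), "unknown")
})

test_that("the index is the weighted merit sum and is order-invariant", {
  w <- c(DMY = 0.35, DFY = 0.175, DPY = 0.175, Fert = 0.10, Res = 0.20)
  m <- matrix(c(1, 0, 0, 0, 1), 1, dimnames = list(NULL, names(w)))
  expect_equal(compute_index(m, w), 0.55)
  # permuting trait columns (with matching weights) changes nothing
  perm <- c("Res", "Fert", "DMY", "DPY", "DFY")
  expect_equal(compute_index(m[, perm, drop = FALSE], w[perm]), 0.55)
  # unweighted traits contribute nothing
  expect_equal(compute_index(m, c(DMY = 1)), 1)
  expect_error(compute_index(m, c(XX = 1)), "XX")

  # all weight on one directional trait ranks exactly by that trait
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(100, ap, seed = 22)
  pop <- simulate_ebv(pop, ap)
  z <- standardize_ebv(pop)
  idx <- compute_index(z, c(A = 1))
  expect_equal(order(idx), order(pop$ebv[, "A"]))
})

test_that("truncation selection takes the stated counts per sex", {
  g <- goat_params()
  ap <- active_parameters(g, "actual")
  pop <- simulate_base_population(1000, ap, seed = 23)
  pop <- simulate_ebv(pop, ap)
  idx <- compute_index(standardize_ebv(pop), c(DMY = 1))
  sel <- select_parents(pop, idx, g$program$prop_male,
                        g$program$prop_female)
  expect_equal(length(sel$sire_idx), 150)  # 30% of 500 males
  expect_equal(length(sel$dam_idx), 250)   # 50% of 500 females
  s <- sheep_params()
  sel2 <- select_parents(pop, idx, s$program$prop_male,
                         s$program$prop_female)
  expect_equal(length(sel2$sire_idx), 50)  # 10% of 500 males
  expect_equal(length(sel2$dam_idx), 250)

  all_sel <- select_parents(pop, idx, 1, 1)
  expect_equal(length(all_sel$sire_idx) + length(all_sel$dam_idx), 1000)

  # selection differential is strictly positive under truncation
  expect_gt(mean(idx[c(sel$sire_idx, sel$dam_idx)]), mean(idx))
  expect_error(select_parents(pop, idx, 0, 0.5), "\\(0, 1\\]")
})

test_that("selection is invariant to positive weight rescaling and ties
           break deterministically", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(80, ap, seed = 24)
  pop <- simulate_ebv(pop, ap)
  z <- standardize_ebv(pop)
  w <- c(A = 0.6, B = 0.4)
  s1 <- select_parents(pop, compute_index(z, w), 0.5, 0.5)
  s2 <- select_parents(pop, compute_index(z, 5 * w), 0.5, 0.5)
  expect_identical(s1$sire_idx, s2$sire_idx)
  expect_identical(s1$dam_idx, s2$dam_idx)

  tied <- rep(0, 80)
  s3 <- select_parents(pop, tied, 0.5, 0.5)
  s4 <- select_parents(pop, tied, 0.5, 0.5)
  expect_identical(s3$sire_idx, s4$sire_idx)
  # with a constant index, the lowest ids of each sex are kept
  expect_identical(s3$sire_idx, which(pop$sex == "M")[1:20])
})
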