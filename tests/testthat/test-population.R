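test_that("base population reproduces the stated phenotypic means", {
  ap <- active_parameters(goat_params(), "actual")
  pop <- simulate_base_population(10000, ap, seed = 1)
  # sample mean within 3 SE of the published mean, per trait
  for (k in colnames(pop$phen)) {
    se <- sqrt(ap$covariance$var_genetic[[k]] +
               ap$covariance$var_residual[[k]]) / sqrt(10000)
    expect_lt(abs(mean(pop$phen[, k]) - ap$traits[[k]]$mean), 3 * se)
  }
  expect_equal(sum(pop$sex == "M"), 5000)
  expect_true(all(pop$f == 0) && all(is.na(pop$sire)))
  expect_error(simulate_base_population(1, ap), ">= 2")
})

test_that("phenotype decomposes exactly into mean + TBV + deviation", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(200, ap, seed = 2)
  mu <- vapply(ap$traits, `[[`, 0, "mean")
  expect_equal(pop$phen, sweep(pop$tbv + pop$env, 2, mu, "+"))
  # with a null residual covariance the phenotype is mean + TBV exactly
  ap0 <- ap
  ap0$E <- matrix(0, 2, 2, dimnames = dimnames(ap$E))
  pop0 <- simulate_base_population(100, ap0, seed = 3)
  expect_equal(sweep(pop0$phen, 2, mu), pop0$tbv)
})

test_that("TBV sampling recovers the genetic covariance", {
  ap <- active_parameters(tiny_params(rho_g = 0.3), "none")
  pop <- simulate_base_population(20000, ap, seed = 4)
  S <- cov(pop$tbv)
  scale <- tcrossprod(sqrt(diag(ap$G0)))
  expect_lt(max(abs(S - ap$G0) / scale), 0.05)
})

test_that("pseudo-EBVs realize their nominal accuracy", {
  ap <- active_parameters(tiny_params(acc = c(A = 1, B = 0.5)), "none")
  pop <- simulate_base_population(20000, ap, seed = 5)
  pop <- simulate_ebv(pop, ap)
  # accuracy 1: perfect rank agreement with the TBVs
  expect_equal(order(pop$ebv[, "A"]), order(pop$tbv[, "A"]))
  expect_lt(abs(cor(pop$ebv[, "B"], pop$tbv[, "B"]) - 0.5), 0.02)
  expect_error(simulate_ebv(pop, ap, accuracies = c(A = 0, B = 0.5)),
               "accurac")
  expect_error(simulate_ebv(pop, ap, accuracies = c(A = 1.01, B = 0.5)),
               "accurac")
})

test_that("Mendelian sampling covariance follows 0.5 G0 (1 - Fbar)", {
  G0 <- active_parameters(goat_params(), "actual")$G0
  expect_equal(mendelian_variance(G0, 0, 0), 0.5 * G0)
  expect_equal(mendelian_variance(G0, 1, 1), 0 * G0)
  expect_equal(mendelian_variance(G0, 0.25, 0), 0.4375 * G0)
  expect_error(mendelian_variance(G0, -0.1, 0), "\\[0, 1\\]")
})

test_that("offspring respect parent caps and the mid-parent expectation", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(400, ap, seed = 6)
  sires <- subset_population(pop, which(pop$sex == "M")[1:5])
  dams <- subset_population(pop, which(pop$sex == "F")[1:80])
  off <- breed_generation(sires, dams, 300, caps = c(sire = 100, dam = 7),
                          params = ap, seed = 7)
  expect_true(all(tabulate(attr(off, "sire_slot"), 5) <= 100))
  expect_true(all(tabulate(attr(off, "dam_slot"), 80) <= 7))
  expect_equal(length(off$id), 300)
  # offspring TBV mean close to the mean mid-parent value
  mid <- 0.5 * (colMeans(sires$tbv) + colMeans(dams$tbv))
  se <- sqrt(diag(0.5 * ap$G0) / 300 + diag(ap$G0) / 50)
  expect_true(all(abs(colMeans(off$tbv) - mid) < 3 * se))
  # binding capacity is reported by name (5 sires, 80 dams)
  expect_error(breed_generation(sires, dams, 600,
                                caps = c(sire = 1000, dam = 7), ap),
               "dam capacity")
  expect_error(breed_generation(sires, dams, 600,
                                caps = c(sire = 100, dam = 100), ap),
               "sire capacity")
})

test_that("fully inbred parents transmit the exact mid-parent TBV", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(10, ap, seed = 8)
  sire <- subset_population(pop, 1L)
  dam <- subset_population(pop, 2L)
  sire$f <- 1
  dam$f <- 1   # Mendelian variance collapses to zero
  off <- breed_generation(sire, dam, 50, caps = c(sire = 50, dam = 50),
                          params = ap, seed = 9)
  mid <- 0.5 * (sire$tbv[1, ] + dam$tbv[1, ])
  for (i in 1:50) expect_equal(off$tbv[i, ], mid)
})

test_that("pedigree inbreeding matches hand-computed closed forms", {
  # founders 1-4; 5,6 are full sibs (1x2); 7 = 5x6 full-sib mating;
  # 8 from 1x3, 9 = 5x8 half-sib mating (common parent 1)
  ped <- data.frame(id = 1:9,
                    sire = c(0, 0, 0, 0, 1, 1, 5, 1, 5),
                    dam = c(0, 0, 0, 0, 2, 2, 6, 3, 8))
  f <- compute_inbreeding(ped)
  expect_equal(unname(f[1:4]), rep(0, 4))
  expect_equal(f[["7"]], 0.25)
  expect_equal(f[["9"]], 0.125)
  expect_error(compute_inbreeding(data.frame(id = 1:2, sire = c(0, 9),
                                             dam = c(0, 0))),
               "unknown parent")
  expect_error(compute_inbreeding(data.frame(id = c(2, 1),
                                             sire = c(1, 0),
                                             dam = c(0, 0))),
               "before")
})

test_that("engine inbreeding agrees with the standalone tabular method", {
  ps <- tiny_params()
  sc <- scenario_spec("sel", c(A = 0.7, B = 0.3), "none")
  run <- run_scenario(ps, sc, generations = 4, replicates = 1,
                      n_animals = 60, seed = 11, record_pedigree = TRUE)
  ped <- run$pedigrees[[1]]
  f <- compute_inbreeding(ped)
  gen <- (ped$id - 1) %/% 60   # ids are laid out per generation
  expect_equal(as.numeric(tapply(f, gen, mean)),
               run$trajectories$mean_f, tolerance = 1e-12)
})

test_that("inbreeding depression lowers the phenotype linearly", {
  ap <- active_parameters(tiny_params(), "none")
  pop <- simulate_base_population(20, ap, seed = 12)
  expect_equal(apply_inbreeding_depression(pop, "A", 0.5)$phen, pop$phen)
  pop$f <- rep(0.10, 20)
  dep <- apply_inbreeding_depression(pop, "A", 0.5)
  expect_equal(dep$phen[, "A"], pop$phen[, "A"] - 0.05)
  expect_equal(dep$tbv, pop$tbv)
  expect_equal(dep$phen[, "B"], pop$phen[, "B"])
  expect_warning(apply_inbreeding_depression(pop, "A", -0.1), "negative")
  expect_error(apply_inbreeding_depression(pop, "Z", 0.5), "not present")
})

test_that("TBV means only drift under random mating", {
  ps <- tiny_params()
  set.seed(13)
  n <- 60L
  gens <- 20L
  hits <- 0L
  total <- 0L
  for (rep in 1:20) {
    rm <- random_mating_run(ps, n, gens, n_sires = n / 2, n_dams = n / 2)
    for (k in colnames(rm$mean_tbv)) {
      sg2 <- ps$covariance$var_genetic[[k]]
      # drift-aware bound: sampling noise plus t/(2Ne) drift variance
      bound <- 4 * sqrt(sg2 * (gens / (2 * n) + 1 / n))
      total <- total + 1L
      hits <- hits + (abs(rm$mean_tbv[gens + 1, k]) < bound)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("inbreeding accumulates at the rate set by Ne", {
  ps <- tiny_params()
  set.seed(14)
  gens <- 10L
  fin <- replicate(4, random_mating_run(ps, 40L, gens, n_sires = 10,
                                        n_dams = 10)$mean_f[gens + 1])
  ne <- 20
  expected <- 1 - (1 - 1 / (2 * ne))^(gens - 1)  # F lags one generation
  expect_gt(mean(fin) / expected, 0.5)
  expect_lt(mean(fin) / expected, 1.6)
})
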