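test_that("built-in parameter sets encode the published values", {
  g <- goat_params()
  expect_equal(g$traits$DMY$mean, 3.59)
  expect_equal(g$traits$DMY$sd, 1.05)
  expect_equal(g$covariance$var_genetic[["Long"]], 11282)
  expect_equal(g$covariance$cor_genetic["DMY", "Mast"], 0.495)
  expect_equal(g$covariance$accuracies[["DMY"]], 0.62)
  expect_equal(g$program$prop_male, 0.30)
  expect_equal(g$economics$values[["Mast"]], -231)

  s <- sheep_params()
  expect_equal(s$covariance$var_genetic[["DPY"]], 82.523)
  expect_equal(s$covariance$var_genetic[["Res"]], 0.020)
  expect_equal(s$covariance$cor_genetic["Fert", "Res"], 0.175)
  expect_equal(s$traits$Fert$mean, 0.42)  # stored as a proportion
  expect_equal(s$program$prop_male, 0.10)
  expect_equal(s$inbreeding_depression$trait, "Fert")
  expect_equal(s$economics$climate_price, 0.076)
})

test_that("covariance assembly applies rho * sqrt(vi * vj)", {
  v <- c(A = 2, B = 3, C = 0.5)
  id <- diag(3)
  dimnames(id) <- list(names(v), names(v))
  expect_equal(assemble_covariance(v, id), diag(v),
               ignore_attr = "dimnames")

  g <- goat_params()
  nm <- c("DMY", "Long", "KA", "Mast", "Res")
  G0 <- assemble_covariance(g$covariance$var_genetic[nm],
                            g$covariance$cor_genetic[nm, nm])
  # diagonals exact, off-diagonals equal the product formula to 1e-12
  expect_identical(diag(G0), g$covariance$var_genetic[nm])
  expect_equal(G0["DMY", "Long"], 0.276 * sqrt(0.370 * 11282),
               tolerance = 1e-12)
  for (i in nm) for (j in nm)
    expect_equal(G0[i, j],
                 g$covariance$cor_genetic[i, j] *
                   sqrt(g$covariance$var_genetic[[i]] *
                        g$covariance$var_genetic[[j]]),
                 tolerance = 1e-12)
  expect_gte(min(eigen(G0, symmetric = TRUE)$values), -1e-8)
})

test_that("indefinite covariance input is repaired by eigenvalue clipping", {
  nm <- c("A", "B", "C")
  v <- c(A = 1, B = 4, C = 9)
  mild <- matrix(c(1, 0.9, 0.9,
                   0.9, 1, 0.45,
                   0.9, 0.45, 1), 3, dimnames = list(nm, nm))
  raw <- mild * tcrossprod(sqrt(v))
  expect_lt(min(eigen(raw)$values), 0)
  expect_message(S <- assemble_covariance(v, mild), "repaired")
  # oracle: clip eigenvalues at zero and restore the diagonal by scaling
  e <- eigen(raw, symmetric = TRUE)
  y <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- sqrt(diag(raw) / diag(y))
  oracle <- y * tcrossprod(d)
  diag(oracle) <- diag(raw)
  expect_equal(S, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-8)
  expect_equal(diag(S), v)

  bad <- matrix(c(1, 0.9, 0.9,
                  0.9, 1, -0.5,
                  0.9, -0.5, 1), 3, dimnames = list(nm, nm))
  expect_error(assemble_covariance(v, bad), "indefinite")
})

test_that("malformed parameters and scenarios are rejected by name", {
  expect_error(trait_spec("X", mean = 1, sd = 0), "sd")
  expect_error(trait_spec("X", mean = 5, sd = 1, bounds = c(0, 4)),
               "bounds")
  expect_error(trait_spec("X", mean = 1, sd = 1, goal = "stabilize"),
               "target")
  expect_error(covariance_spec(c(A = 1), c(A = 1),
                               matrix(1, 1, 1, dimnames = list("A", "A")),
                               matrix(1, 1, 1, dimnames = list("A", "A")),
                               accuracies = c(A = 1.2)),
               "accuracies")
  asym <- matrix(c(1, 0.5, -0.5, 1), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(assemble_covariance(c(A = 1, B = 1), asym), "symmetric")
  expect_error(.params_from_list(list(zone = "z", traits = list())),
               "empty|lacks")

  g <- goat_params()
  expect_error(scenario_spec("neg", c(DMY = -0.1, Long = 1.1)),
               "negative")
  expect_error(scenario_spec("zero", c(DMY = 0, Long = 0)), "zero")
  expect_error(
    validate_scenario(scenario_spec("both", c(Res = 0.5, Stab = 0.5),
                                    "actual"), g),
    "both resilience")
  expect_error(
    validate_scenario(scenario_spec("who", c(DMY = 0.5, XYZ = 0.5)), g),
    "XYZ")
})

test_that("weights are accepted on percent or proportion scale", {
  a <- scenario_spec("pct", c(DMY = 35, DFY = 17.5, DPY = 17.5,
                              Fert = 10, Res = 20), "actual")
  b <- scenario_spec("prop", c(DMY = 0.35, DFY = 0.175, DPY = 0.175,
                               Fert = 0.10, Res = 0.20), "actual")
  expect_equal(a$weights, b$weights)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
  v <- validate_scenario(a, sheep_params())
  expect_equal(sum(v$weights), 1, tolerance = 1e-12)
})

test_that("parameter sets round-trip through the YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  g <- goat_params()
  write_parameter_set(g, path)
  g2 <- load_parameter_set(path, check = FALSE)
  expect_equal(g2, g, tolerance = 1e-9)

  t1 <- tiny_params()
  write_parameter_set(t1, path)
  expect_equal(load_parameter_set(path, check = FALSE), t1,
               tolerance = 1e-9)
})

test_that("phenotypic SDs are cross-checked against variance components", {
  # shipped sheep set: descriptive SDs include variation beyond the
  # fitted components, so the check must warn (and not error)
  expect_warning(load_parameter_set("mediterranean-sheep"),
                 "inconsistent")
  # a set built to be consistent stays silent
  expect_silent(check_phenotypic_consistency(tiny_params()))
})
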