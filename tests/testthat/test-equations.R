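test_that("OLS refit recovers exact linear relationships", {
  v <- cbind(S1 = c(1, 2, 3, 4, 5), Y9 = 2 + 3 * c(1, 2, 3, 4, 5))
  eq <- suppressWarnings(fit_ols(toy_dataset(v), "Y9", "S1"))
  expect_equal(eq$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(eq$coefficients["S1"]), 3, tolerance = 1e-10)
  expect_equal(eq$r_squared, 1, tolerance = 1e-12)
})

test_that("OLS coefficients, F and p match the normal-equations and F-CDF oracles", {
  d <- make_study_like_dataset(n = 30, seed = 41)
  sel <- c("C1", "C2", "S1", "S5", "S9")
  eq <- fit_ols(d, "Y9", sel)
  X <- d$values[, sel]
  y <- d$values[, "Y9"]
  beta <- ols_oracle(X, y)
  expect_equal(eq$intercept, unname(beta[1]), tolerance = 1e-8)
  expect_equal(unname(eq$coefficients), unname(beta[-1]), tolerance = 1e-8)
  # residual orthogonality to the design
  res <- y - cbind(1, X) %*% beta
  expect_lt(max(abs(crossprod(cbind(1, X), res))), 1e-6)
  # R^2 equals squared correlation of fitted vs observed
  fitted <- drop(cbind(1, X) %*% beta)
  expect_equal(eq$r_squared, cor(fitted, y)^2, tolerance = 1e-10)
  # F and p from the stated formulas
  n <- 30; k <- length(sel)
  F_o <- (eq$r_squared / k) / ((1 - eq$r_squared) / (n - k - 1))
  expect_equal(eq$F, F_o, tolerance = 1e-10)
  expect_equal(eq$p_value, pf(F_o, k, n - k - 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("a permuted response yields a p-value matching the F distribution oracle", {
  d <- make_study_like_dataset(n = 99, seed = 43)
  set.seed(43)
  v <- d$values
  v[, "Y1"] <- sample(v[, "Y1"])
  sel <- c("C2", "S3", "S5", "S6", "S10", "S12")
  eq <- fit_ols(orchard_dataset(v), "Y1", sel)
  expect_equal(eq$p_value, pf(eq$F, 6, 92, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_gt(eq$p_value, 0)
  expect_lte(eq$p_value, 1)
})

test_that("equation evaluation reproduces published worked examples and errors on gaps", {
  sys <- table4_equations()
  y5 <- evaluate_equation(sys$equations[["Y5"]],
                          c(C1 = 1855.20, C2 = 20.93, T1 = 524.00,
                            T2 = 29.11, S7 = 6.98))
  expect_equal(round(y5, 2), 76.25)
  y9 <- evaluate_equation(sys$equations[["Y9"]],
                          c(S1 = 7.50, S9 = 0.46, S11 = 2.66, S12 = 4.00))
  expect_equal(round(y9, 2), 0.49)
  # all factors zero -> intercept
  zeros <- setNames(rep(0, 16), factor_codes())
  expect_equal(evaluate_equation(sys$equations[["Y1"]], zeros), -471.633)
  expect_error(evaluate_equation(sys$equations[["Y9"]], c(S1 = 7.5)),
               "S9")
})

test_that("the packaged equation system matches its published coefficients digit for digit", {
  sys <- table4_equations()
  expect_equal(length(sys$equations), 11)
  expect_equal(sys$provenance, "packaged-table-4")
  expect_equal(sum(lengths(lapply(sys$equations, `[[`, "coefficients"))), 59)
  y1 <- sys$equations[["Y1"]]
  expect_identical(y1$intercept, -471.633)
  expect_identical(unname(y1$coefficients),
                   c(36.999, 0.637, -3.499, 0.184, 0.93, 9.681))
  expect_identical(names(y1$coefficients),
                   c("C2", "S3", "S5", "S6", "S10", "S12"))
  y9 <- sys$equations[["Y9"]]
  expect_identical(unname(y9$coefficients), c(-0.112, 0.612, 0.001, -0.133))
  expect_identical(sys$equations[["Y4"]]$coefficients[["T1"]], -0.00002)
  expect_equal(vapply(sys$equations, `[[`, numeric(1), "F")[c("Y1", "Y5")],
               c(Y1 = 4.35, Y5 = 8.09))
})

test_that("system building drops empty selections with a warning and recovers truth at zero noise", {
  cfg <- generator_config(n_samples = 60, seed = 47, noise_sd = 0)
  d <- generate_traits(sample_factors(cfg), cfg)
  gen <- table4_equations()
  screens <- lapply(c("Y1", "Y9"), function(tr)
    structure(list(trait = tr,
                   selected = names(gen$equations[[tr]]$coefficients)),
              class = "screen_result"))
  screens[[3]] <- structure(list(trait = "Y2", selected = character(0)),
                            class = "screen_result")
  w <- capture_warnings(sys <- build_system(d, screens))
  expect_true(any(grepl("Y2", w)))
  expect_equal(length(sys$equations), 2)
  for (tr in c("Y1", "Y9")) {
    expect_equal(sys$equations[[tr]]$coefficients,
                 gen$equations[[tr]]$coefficients, tolerance = 1e-6)
    expect_equal(sys$equations[[tr]]$intercept, gen$equations[[tr]]$intercept,
                 tolerance = 1e-6)
  }
})

test_that("equation systems serialize and reload exactly", {
  cfg <- generator_config(n_samples = 50, seed = 53)
  d <- generate_traits(sample_factors(cfg), cfg)
  sys <- build_system(d, list(
    structure(list(trait = "Y1", selected = c("C2", "S3")),
              class = "screen_result")))
  p <- withr::local_tempfile(fileext = ".csv")
  write_equation_system(sys, p)
  sys2 <- read_equation_system(p)
  expect_equal(sys2$equations[["Y1"]]$coefficients,
               sys$equations[["Y1"]]$coefficients, tolerance = 0)
  expect_equal(sys2$equations[["Y1"]]$F, sys$equations[["Y1"]]$F,
               tolerance = 1e-12)
})

test_that("ill-posed OLS designs are rejected", {
  d <- make_study_like_dataset(n = 5, seed = 59)
  expect_error(fit_ols(d, "Y1", character(0)), "empty selection")
  expect_error(fit_ols(d, "Y1", c("C1", "C2", "S1", "S2", "S3")), "n > k")
  v <- d$values
  v <- cbind(v[, c("C1", "Y1"), drop = FALSE], S1 = v[, "C1"] * 2)
  expect_error(fit_ols(orchard_dataset(v), "Y1", c("C1", "S1")), "singular")
})
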