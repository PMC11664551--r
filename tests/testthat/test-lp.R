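test_that("trivial box programs solve exactly", {
  s <- navelopt:::simplex_solve(1, matrix(1, 1, 1), "<=", 1, maximize = TRUE)
  expect_equal(s$status, "optimal")
  expect_equal(s$value, 1)
  s2 <- navelopt:::simplex_solve(c(1, 0), rbind(c(1, 0), c(0, 1)),
                                 c("<=", "<="), c(5, 2), maximize = FALSE)
  expect_equal(s2$value, 0)
})

test_that("infeasible and unbounded programs are reported honestly", {
  inf <- navelopt:::simplex_solve(1, rbind(1, 1), c("<=", ">="), c(1, 2),
                                  maximize = TRUE)
  expect_equal(inf$status, "infeasible")
  unb <- navelopt:::simplex_solve(1, matrix(1, 1, 1), ">=", 1,
                                  maximize = TRUE)
  expect_equal(unb$status, "unbounded")
})

test_that("simplex optima equal the vertex-enumeration oracle on random bounded programs", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    A <- rbind(diag(n), matrix(round(rnorm(3 * n), 2), 3, n))
    dir <- c(rep("<=", n), sample(c("<=", ">="), 3, replace = TRUE))
    rhs <- c(rep(1, n), round(runif(3, -0.5, 1.5), 2))
    obj <- round(rnorm(n), 2)
    maxi <- sample(c(TRUE, FALSE), 1)
    o <- vertex_lp_oracle(obj, A, dir, rhs, maxi)
    s <- navelopt:::simplex_solve(obj, A, dir, rhs, maximize = maxi)
    if (is.null(o$x)) {
      expect_equal(s$status, "infeasible", label = paste("rep", rep))
    } else {
      expect_equal(s$status, "optimal", label = paste("rep", rep))
      expect_equal(s$value, o$value, tolerance = 1e-8,
                   label = paste("rep", rep))
    }
  }
})

test_that("building a program wires senses, constraints and the box correctly", {
  sys <- table4_equations()
  p1 <- build_lp(sys, "Y1")
  expect_equal(p1$sense, "maximize")
  expect_equal(length(p1$constraints), 10)
  expect_equal(nrow(p1$box), 16)
  expect_false("Y1" %in% names(p1$constraints))
  expect_equal(p1$constraints[["Y9"]]$direction, "<=")
  expect_equal(p1$constraints[["Y2"]]$direction, ">=")
  expect_equal(p1$constraints[["Y2"]]$bound, 83.56)
  p4 <- build_lp(sys, "Y4")
  expect_equal(p4$sense, "minimize")
  expect_error(build_lp(sys, "TSS"), "not in the equation system")

  # two-trait toy system: exactly one trait constraint
  toy <- equation_system(list(
    linear_equation("Y1", 0, c(S1 = 1)),
    linear_equation("Y9", 1, c(S1 = -0.1))))
  pt <- build_lp(toy, "Y1")
  expect_equal(names(pt$constraints), "Y9")
})

test_that("every returned solution is feasible and dominates random feasible points", {
  sys <- table4_equations()
  bounds <- default_bounds()
  res <- optimize_all(sys, bounds)
  expect_true(all(vapply(res$solutions, function(s) s$status, character(1)) ==
                    "optimal"))
  lo <- setNames(bounds$factor_bounds$lower, bounds$factor_bounds$code)
  hi <- setNames(bounds$factor_bounds$upper, bounds$factor_bounds$code)
  for (tr in names(res$solutions)) {
    s <- res$solutions[[tr]]
    x <- s$factor_values
    expect_true(all(x >= lo[names(x)] - 1e-6 & x <= hi[names(x)] + 1e-6),
                label = tr)
    for (cn in build_lp(sys, tr, bounds)$constraints) {
      val <- evaluate_equation(cn$equation, x)
      if (cn$direction == ">=") expect_gte(val, cn$bound - 1e-6)
      else expect_lte(val, cn$bound + 1e-6)
    }
  }
  # rejection-sample feasible points in the box; none may beat the optimum
  set.seed(67)
  fac <- factor_codes()
  cand <- sapply(fac, function(f) runif(1000, lo[f], hi[f]))
  feas <- rep(TRUE, 1000)
  vals <- list()
  for (tr in names(sys$equations)) {
    v <- apply(cand, 1, function(row)
      evaluate_equation(sys$equations[[tr]], setNames(row, fac)))
    vals[[tr]] <- v
    tb <- bounds$trait_bounds[bounds$trait_bounds$trait == tr, ]
    feas <- feas & (if (tb$direction == ">=") v >= tb$bound else v <= tb$bound)
  }
  for (tr in names(res$solutions)) {
    opt <- res$solutions[[tr]]$objective_value
    v <- vals[[tr]][feas]
    if (length(v) > 0) {
      if (trait_sense(tr) == "maximize") expect_gte(opt, max(v) - 1e-6)
      else expect_lte(opt, min(v) + 1e-6)
    }
  }
})

test_that("the optimal range table reflects per-factor spread across objectives", {
  res <- optimize_all(table4_equations())
  rt <- res$range_table
  expect_equal(nrow(rt), 16)
  expect_true(all(rt$range_lower <= rt$range_upper + 1e-12))
  # exchangeable Mg pins to its upper bound wherever its value is determined;
  # in the b* program it is an alternative optimum (absent from that
  # equation), so fixing it at 4.00 must leave the optimum unchanged
  s12 <- unlist(rt[rt$code == "S12", paste0("Y", 1:11)])
  free <- names(s12)[abs(s12 - 4) > 1e-8]
  expect_lte(length(free), 1)
  expect_equal(unname(s12[setdiff(names(s12), free)]),
               rep(4, 11 - length(free)), tolerance = 1e-8)
  bounds <- default_bounds()
  fb <- bounds$factor_bounds
  fb$lower[fb$code == "S12"] <- 4
  for (tr in free) {
    pinned <- solve_lp(build_lp(table4_equations(), tr,
                                bounds_spec(fb, bounds$trait_bounds)))
    expect_equal(pinned$objective_value,
                 res$solutions[[tr]]$objective_value, tolerance = 1e-8)
  }
  bounds <- default_bounds()
  lo <- setNames(bounds$factor_bounds$lower, bounds$factor_bounds$code)
  hi <- setNames(bounds$factor_bounds$upper, bounds$factor_bounds$code)
  expect_true(all(rt$range_lower >= lo[rt$code] - 1e-8))
  expect_true(all(rt$range_upper <= hi[rt$code] + 1e-8))
})

test_that("a factor fixed by its box is constant and collapsed across solutions", {
  bounds <- default_bounds()
  fb <- bounds$factor_bounds
  fb$upper[fb$code == "S1"] <- fb$lower[fb$code == "S1"]
  res <- optimize_all(table4_equations(), bounds_spec(fb, bounds$trait_bounds))
  ok <- vapply(res$solutions, function(s) s$status == "optimal", logical(1))
  rt <- res$range_table
  s1 <- rt[rt$code == "S1", ]
  expect_equal(s1$range_lower, s1$range_upper)
  expect_equal(s1$range_lower, fb$lower[fb$code == "S1"])
})

test_that("unconstrained factors are flagged as possibly non-unique", {
  res <- optimize_all(table4_equations())
  # clay (S2) appears in no equation: arbitrary within its box in every program
  for (s in res$solutions) expect_true("S2" %in% s$nonunique)
})
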