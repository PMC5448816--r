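test_that("a small LP with a known vertex optimum is solved", {
  # max 3x + 2y  s.t.  x + y <= 4, x <= 2, x,y >= 0  ->  (2, 2), objective 10
  lp <- linear_program(c("x", "y"), c(0, 0), c(Inf, Inf),
                       row_i = c(1L, 1L, 2L), row_j = c(1L, 2L, 1L),
                       row_x = c(1, 1, 1),
                       row_lb = c(-Inf, -Inf), row_ub = c(4, 2),
                       obj = c(3, 2), maximize = TRUE)
  s <- solve_lp(lp)
  expect_equal(s$status, "optimal")
  expect_equal(s$objval, 10)
  expect_equal(unname(s$x), c(2, 2))
})

test_that("equality rows and free variables are honoured", {
  # min x + y  s.t.  x - y = 3, x >= 0, y free  ->  y = -3 unbounded? no:
  # min over x>=0, y = x - 3: objective 2x - 3, optimum x = 0, y = -3
  lp <- linear_program(c("x", "y"), c(0, -Inf), c(Inf, Inf),
                       row_i = c(1L, 1L), row_j = c(1L, 2L), row_x = c(1, -1),
                       row_lb = 3, row_ub = 3,
                       obj = c(1, 1), maximize = FALSE)
  s <- solve_lp(lp)
  expect_equal(s$status, "optimal")
  expect_equal(s$objval, -3)
  expect_equal(unname(s$x), c(0, -3))
})

test_that("infeasible and unbounded problems are reported as such", {
  infeas <- linear_program("x", 0, 1,
                           row_i = 1L, row_j = 1L, row_x = 1,
                           row_lb = 3, row_ub = Inf)
  expect_equal(solve_lp(infeas)$status, "infeasible")

  unb <- linear_program("x", 0, Inf, obj = 1, maximize = TRUE)
  expect_equal(solve_lp(unb)$status, "unbounded")
})

test_that("LP modification helpers validate and apply changes", {
  lp <- linear_program(c("x", "y"), c(0, 0), c(10, 10))
  lp2 <- lp_set_objective(lp, c(x = 1), maximize = TRUE)
  expect_equal(solve_lp(lp2)$objval, 10)
  lp3 <- lp_set_var_bounds(lp2, "x", 2, 2)
  expect_equal(solve_lp(lp3)$x[["x"]], 2)
  lp4 <- lp_add_row(lp2, c(x = 1, y = 1), -Inf, 5)
  lp4 <- lp_set_objective(lp4, c(x = 1, y = 1), maximize = TRUE)
  expect_equal(solve_lp(lp4)$objval, 5)

  expect_error(lp_set_objective(lp, c(z = 1)), "unknown variable")
  expect_error(lp_set_var_bounds(lp, "z", 0, 1), "unknown variable")
  expect_error(lp_add_row(lp, c(z = 1), 0, 0), "unknown variable")
  expect_error(lp_set_var_bounds(lp, "x", 2, 1), "exceeds")
  expect_error(linear_program("x", 0, 1, row_i = 1L, row_j = 2L, row_x = 1,
                              row_lb = 0, row_ub = 0), "undeclared")
})
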