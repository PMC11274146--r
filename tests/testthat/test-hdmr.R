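test_that("dimensions the model ignores get zero weight and drop from S", {
  sp <- default_space()
  f <- function(x) { s <- rel_coords(x); 3 + s[2]^2 }
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 1)
  expect_equal(surr$eta[1], 0)
  expect_false(1 %in% surr$important)
  expect_true(2 %in% surr$important)   # eta_2 = (1/3)/3 > 1e-2
})

test_that("importance weights reproduce the analytic uniform moments", {
  sp <- default_space()
  # F = 10 + s1^2: E[F_1] = 1/3, so eta_1 = 1/30
  f <- function(x) 10 + rel_coords(x)[1]^2
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 1)
  expect_equal(surr$eta[1], 1 / 30, tolerance = 1e-12)
  expect_true(1 %in% surr$important)

  # odd dependence is invisible to the signed-mean weight as defined
  g <- function(x) 10 + rel_coords(x)[1]
  sg <- build_hdmr(g, sp, n_gl = 3, max_order = 1)
  expect_lt(sg$eta[1], 1e-15)
  # ... but the variance-based alternative weight sees it
  sv <- build_hdmr(g, sp, n_gl = 3, max_order = 1, weight = "variance")
  expect_gt(sv$eta[1], 1e-2)

  expect_error(importance_weights(c(0, 0), sg$first_order), "degenerate")
})

test_that("additive models produce numerically null pair components", {
  sp <- default_space()
  f <- function(x) { s <- rel_coords(x); 2 + sum(s^2) }
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 2)
  expect_equal(length(surr$important), 12)    # eta_i = (1/3)/2 each
  expect_equal(length(surr$second_order), 66)
  pair_norms <- vapply(surr$second_order, function(comp) {
    sqrt(sum(Mod(comp$coefficients)^2))
  }, numeric(1))
  expect_lt(max(pair_norms), 1e-10)

  # additive variance decomposition: first-order variances sum to the total
  v1 <- sum(hdmr_first_order_variances(surr))
  pts <- design_matrix(sample_uniform(sp, 2e4, seed = 8))
  vtot <- var(as.vector(evaluate_hdmr(surr, pts)))
  expect_equal(v1, vtot, tolerance = 0.05)
})

test_that("the evaluation ledger equals the collocation-count formula", {
  sp <- default_space()
  f <- function(x) { s <- rel_coords(x); 2 + sum(s^2) + 0.05 * s[1] * s[2] }
  for (cfg in list(list(o = 1, g = 3), list(o = 2, g = 3), list(o = 2, g = 5))) {
    surr <- build_hdmr(f, sp, n_gl = cfg$g, max_order = cfg$o)
    n_pairs <- length(surr$second_order)
    expect_equal(
      attr(surr$ledger, "total"),
      count_collocation_points(12, n_pairs, cfg$g, cfg$o)
    )
    # the cache saw exactly that many distinct input vectors
    expect_equal(nrow(attr(surr$ledger, "unique_points")),
                 attr(surr$ledger, "total"))
    expect_equal(sum(surr$ledger$new_points), attr(surr$ledger, "total"))
  }
  expect_equal(count_collocation_points(12, 0, 3, 1), 25L)
  expect_equal(count_collocation_points(12, 66, 3, 2), 289L)
  expect_equal(count_collocation_points(12, 66, 5, 2), 1105L)
  expect_error(count_collocation_points(12, 67, 3, 2))
})

test_that("components anchor at the reference point and the surrogate returns f0 there", {
  sp <- default_space()
  ref <- reference_point(sp)
  f <- function(x) { s <- rel_coords(x); 5 + s[1] + s[3]^2 + 0.3 * s[2] * s[4] }
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 2, tol = -1)
  f0_norm <- sqrt(sum(Mod(surr$f0)^2))
  for (comp in c(surr$first_order, surr$second_order)) {
    at_ref <- evaluate_gpc(comp, matrix(ref[comp$subset], 1))
    expect_lt(max(Mod(at_ref)) / f0_norm, 1e-10)
  }
  expect_equal(as.vector(evaluate_hdmr(surr, matrix(ref, 1))), surr$f0,
               tolerance = 1e-12)
})

test_that("functions with exact second-order structure are reproduced to machine precision", {
  sp <- default_space()
  set.seed(31)
  for (rep in 1:3) {
    a <- rnorm(12); b <- rnorm(12); cc <- matrix(rnorm(144), 12)
    f <- function(x) {
      s <- rel_coords(x)
      3 + sum(a * s) + sum(b * s^2) +
        sum(cc[upper.tri(cc)] * outer(s, s)[upper.tri(cc)])
    }
    surr <- build_hdmr(f, sp, n_gl = 3, max_order = 2, tol = -1)
    pts <- design_matrix(sample_uniform(sp, 100, seed = rep))
    pred <- as.vector(evaluate_hdmr(surr, pts))
    truth <- apply(pts, 1, f)
    expect_lt(max(abs(pred - truth) / abs(truth)), 1e-8)
  }
})

test_that("first-order component variances match the uniform closed form", {
  sp <- default_space()
  box <- param_box(sp)
  f <- function(x) x[1]
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 1, tol = -1)
  v <- hdmr_first_order_variances(surr)
  expect_equal(v[1, 1], (box[1, 2] - box[1, 1])^2 / 12, tolerance = 1e-10)
  expect_lt(max(v[-1, ]), 1e-20)
})

test_that("planned evaluation tables rebuild the identical surrogate", {
  sp <- default_space()
  f <- function(x) { s <- rel_coords(x); 2 + s[1]^2 + 0.5 * s[1] * s[2] + s[2]^2 }
  plan <- hdmr_plan(sp, n_gl = 3, max_order = 2)
  expect_equal(nrow(plan), count_collocation_points(12, 66, 3, 2))
  pts <- as.matrix(plan[setdiff(names(plan), "point_id")])
  vals <- matrix(apply(pts, 1, f), ncol = 1)
  rebuilt <- build_hdmr(tabulated_model(plan, vals), sp, n_gl = 3,
                        max_order = 2, tol = -1)
  direct <- build_hdmr(f, sp, n_gl = 3, max_order = 2, tol = -1)
  expect_equal(rebuilt$f0, direct$f0)
  expect_equal(rebuilt$first_order[[1]]$coefficients,
               direct$first_order[[1]]$coefficients)
  # a point outside the plan is refused
  bad <- tabulated_model(plan, vals)
  expect_error(bad(reference_point(sp) * 1.01), "not in the evaluation table")
})

test_that("broom-style accessors summarize the build", {
  sp <- default_space()
  f <- function(x) { s <- rel_coords(x); 1 + s[1]^2 + s[2]^2 }
  surr <- build_hdmr(f, sp, n_gl = 3, max_order = 2)
  g <- glance(surr)
  expect_equal(g$n_dims, 12)
  expect_equal(g$ncp, attr(surr$ledger, "total"))
  td <- tidy(surr)
  expect_equal(nrow(td), 1 + 12 + length(surr$second_order))
  expect_equal(sum(td$new_points), g$ncp)
  expect_equal(td$eta[td$component == "F1"], surr$eta[1])
})
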