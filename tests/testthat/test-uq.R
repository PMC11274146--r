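test_that("MC statistics recover constants and uniform closed forms", {
  sp <- default_space()
  cst <- mc_statistics(function(x) c(4, -2), sp, n = 200, seed = 1)
  expect_equal(as.vector(cst$mean), c(4, -2))
  expect_equal(as.vector(cst$variance), c(0, 0))

  box <- param_box(sp)
  st <- mc_statistics(function(x) x[1], sp, n = 1e4, seed = 7)
  closed <- (box[1, 2] - box[1, 1])^2 / 12
  se_var <- closed * sqrt(2 / st$n)   # normal-theory scale of Var-hat noise
  expect_lt(abs(st$variance - closed), 3 * se_var)
  expect_equal(max(st$trace$n), 1e4)
  expect_equal(nrow(st$trace), 1e4 / 50)

  # identical seeds give identical runs
  st2 <- mc_statistics(function(x) x[1], sp, n = 1e4, seed = 7)
  expect_identical(st$mean, st2$mean)
  expect_identical(st$trace, st2$trace)
})

test_that("the MC mean converges at the 1/sqrt(n) rate", {
  sp <- default_space()
  f <- structure(function(points, outputs = NULL) {
    s <- sweep(points, 2, reference_point(sp), "-")
    matrix(rowSums(s^2 / reference_point(sp)^2), ncol = 1)
  }, class = c("batched_evaluator", "function"))
  sizes <- c(100, 1000, 10000)
  spread <- vapply(sizes, function(n) {
    means <- vapply(1:20, function(r) {
      as.vector(mc_statistics(f, sp, n = n, seed = 100 + r,
                              trace_outputs = integer(0))$mean)
    }, numeric(1))
    var(means)
  }, numeric(1))
  # variance of the mean scales as 1/n: log-log slope near -1, and the
  # hundred-fold range of n shrinks the spread by two orders of magnitude
  slope <- coef(lm(log(spread) ~ log(sizes)))[2]
  expect_gt(slope, -1.5)
  expect_lt(slope, -0.5)
  expect_lt(spread[3] / spread[1], 1 / 100 * 4)
  expect_gt(spread[3] / spread[1], 1 / 100 / 4)
})

test_that("cut-based Sobol indices match analytic variance ratios", {
  sp <- default_space()
  ref <- reference_point(sp)
  # equal-range additive model: each dimension owns half the variance
  f <- function(x) (x[1] - ref[1]) / ref[1] + (x[2] - ref[2]) / ref[2]
  s <- sobol_cut(f, sp, k = c(1, 2, 7), n = 4000, seed = 3)
  expect_equal(unname(s[1, 1]), 0.5, tolerance = 0.05)
  expect_equal(unname(s[2, 1]), 0.5, tolerance = 0.05)
  expect_lt(s[3, 1], 1e-12)   # independent dimension

  # fully additive model: indices sum to one within MC error
  fa <- function(x) sum((x - ref) / ref)
  sa <- sobol_cut(fa, sp, n = 3000, seed = 5)
  expect_equal(sum(sa), 1, tolerance = 0.1)

  # agreement with the HDMR per-dimension cut variances on additive models
  surr <- build_hdmr(function(x) 2 + sum(rel_coords(x)^2), sp,
                     n_gl = 3, max_order = 1)
  v1 <- hdmr_first_order_variances(surr)
  sh <- sobol_cut(surr, sp, n = 4000, seed = 9)
  expect_equal(as.vector(unclass(sh)[, 1]),
               as.vector(v1 / sum(v1)), tolerance = 0.1)

  expect_warning(sobol_cut(function(x) 1, sp, k = 1, n = 100, seed = 1),
                 "zero full variance")
})

test_that("tissue-averaged Sobol indices are exact group means", {
  per_voxel <- rbind(a = c(0.3, 0.3, 0.2, 0.4), b = c(0.1, 0.5, 0.3, 0.3))
  labels <- c(1L, 1L, 2L, 2L)
  tbl <- tissue_averaged_sobol(per_voxel, labels, tissue_names = c("wm", "gm"))
  expect_equal(tbl$sobol[tbl$input == "a" & tbl$tissue == "wm"], 0.3)
  expect_equal(tbl$sobol[tbl$input == "a" & tbl$tissue == "gm"], 0.3)
  expect_equal(tbl$sobol[tbl$input == "b" & tbl$tissue == "wm"], 0.3)

  # independent group-by oracle on random data
  set.seed(21)
  pv <- matrix(runif(12 * 40), 12)
  rownames(pv) <- paste0("x", 1:12)
  lab <- sample(1:3, 40, replace = TRUE)
  got <- tissue_averaged_sobol(pv, lab)
  for (t in 1:3) {
    oracle <- apply(pv[, lab == t, drop = FALSE], 1, mean)
    expect_equal(got$sobol[got$tissue == as.character(t)], unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("error reports implement the per-voxel test-point average", {
  r <- relative_error_report(truth = matrix(c(1, 2), 2, 1),
                             predicted = matrix(c(1.1, 1.9), 2, 1))
  expect_equal(r$per_voxel, (0.1 / 1 + 0.1 / 2) / 2)
  expect_equal(r$err_ave, 0.075)
  expect_equal(r$err_max, 0.075)

  rp <- relative_error_report(matrix(1:6, 2), matrix(1:6, 2))
  expect_equal(rp$err_ave, 0)
  expect_equal(rp$threshold_exceedance, 0)

  # two-loop oracle and voxel-permutation invariance
  set.seed(3)
  truth <- matrix(runif(5 * 8, 1, 2), 5)
  pred <- truth * (1 + matrix(rnorm(40, 0, 0.02), 5))
  r2 <- relative_error_report(truth, pred)
  oracle <- numeric(8)
  for (i in 1:8) {
    acc <- 0
    for (n in 1:5) acc <- acc + abs(truth[n, i] - pred[n, i]) / abs(truth[n, i])
    oracle[i] <- acc / 5
  }
  expect_equal(r2$per_voxel, oracle, tolerance = 1e-12)
  expect_equal(r2$err_ave, mean(oracle), tolerance = 1e-12)
  perm <- sample(8)
  r3 <- relative_error_report(truth[, perm], pred[, perm])
  expect_equal(r3$err_ave, r2$err_ave)
  expect_equal(r3$err_max, r2$err_max)

  # near-zero voxels are guarded out of err_max but reported
  truth_g <- cbind(truth, 1e-9)
  pred_g <- cbind(pred, 2e-9)
  rg <- relative_error_report(truth_g, pred_g)
  expect_equal(rg$excluded, 9L)
  expect_equal(rg$err_max, r2$err_max)
  expect_gt(rg$err_ave, rg$err_ave_guarded)

  expect_error(relative_error_report(truth, pred[, 1:3]), "shape mismatch")
})
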