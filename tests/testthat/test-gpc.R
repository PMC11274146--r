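test_that("1-D Legendre bases are orthonormal under the uniform density", {
  phi0 <- legendre_orthonormal_1d(0, c(2.5, 7))
  expect_equal(phi0(c(2.5, 3, 7)), rep(1, 3))

  phi1 <- legendre_orthonormal_1d(1, c(-1, 1))
  expect_equal(phi1(1), sqrt(3))

  # Gram matrix of degrees 0..4 under a 9-point rule is the identity
  rule <- gl_rule(9, list(c(-2, 5)))
  design <- vapply(0:4, function(d) {
    legendre_orthonormal_1d(d, c(-2, 5))(rule$nodes[, 1])
  }, numeric(9))
  gram <- t(design * rule$weights) %*% design
  expect_lt(max(abs(gram - diag(5))), 1e-10)

  expect_error(legendre_orthonormal_1d(1, c(3, 3)), "degenerate")
})

test_that("total-degree multi-index sets enumerate correctly", {
  mi <- total_degree_multi_indices(2, 2)
  expect_equal(nrow(mi), 6)
  got <- apply(mi, 1, paste, collapse = ",")
  expect_setequal(got, c("0,0", "1,0", "0,1", "1,1", "2,0", "0,2"))
  expect_equal(mi[1, ], c(0L, 0L))  # constant term first

  expect_equal(total_degree_multi_indices(1, 2),
               matrix(0:2, ncol = 1))
  expect_equal(nrow(total_degree_multi_indices(3, 3)), 20)
  for (nv in 1:3) {
    for (p in 0:4) {
      expect_equal(nrow(total_degree_multi_indices(nv, p)), choose(nv + p, p))
    }
  }
})

test_that("tensor Gauss-Legendre rules are probability-normalized and exact", {
  r1 <- gl_rule(1, list(c(2, 6)))
  expect_equal(r1$nodes[1, 1], 4)
  expect_equal(r1$weights, 1)

  r3 <- gl_rule(3, list(c(0, 1)))
  expect_equal(sum(r3$weights), 1, tolerance = 1e-12)
  # mean of x^5 over [0,1] is 1/6; a 3-point rule is exact to degree 5
  expect_equal(sum(r3$nodes[, 1]^5 * r3$weights), 1 / 6, tolerance = 1e-12)

  r2d <- gl_rule(3, list(c(-1, 1), c(0, 4)))
  expect_equal(nrow(r2d$nodes), 9)
  expect_true(any(r2d$nodes[, 1] == 0 & r2d$nodes[, 2] == 2))
  expect_equal(sum(r2d$weights), 1, tolerance = 1e-12)

  # quadrature exactness up to degree 2*n_gl - 1 on a generic interval
  for (n_gl in c(3, 5, 7)) {
    r <- gl_rule(n_gl, list(c(-0.7, 1.3)))
    for (d in 0:(2 * n_gl - 1)) {
      exact <- (1.3^(d + 1) - (-0.7)^(d + 1)) / ((d + 1) * 2)
      expect_equal(sum(r$nodes[, 1]^d * r$weights), exact, tolerance = 1e-12)
    }
  }
  expect_error(gl_rule(4, list(c(0, 1))), "odd")
})

test_that("gPC fitting recovers constants, basis functions, and products", {
  rule <- gl_rule(3, list(c(-1, 1), c(-1, 1)))

  cexp <- fit_gpc(rep(2.5, 9), rule, p = 2)
  expect_equal(as.vector(cexp$coefficients[1, ]), 2.5)
  expect_lt(max(abs(cexp$coefficients[-1, ])), 1e-12)
  expect_equal(as.vector(evaluate_gpc(cexp, cbind(0.4, -0.9))), 2.5)

  # model equal to one orthonormal basis function -> unit coefficient
  basis <- total_degree_multi_indices(2, 2)
  m <- which(basis[, 1] == 1L & basis[, 2] == 1L)  # the (1,1) product term
  vals <- 3 * rule$nodes[, 1] * rule$nodes[, 2]    # phi1 * phi1
  bexp <- fit_gpc(vals, rule, p = 2)
  alpha <- as.vector(bexp$coefficients)
  expect_equal(alpha[m], 1, tolerance = 1e-10)
  expect_lt(max(abs(alpha[-m])), 1e-10)

  # bivariate x1 x2 reconstructed exactly at random points
  pexp <- fit_gpc(rule$nodes[, 1] * rule$nodes[, 2], rule, p = 2)
  set.seed(1)
  pts <- matrix(runif(100, -1, 1), ncol = 2)
  expect_lt(max(abs(evaluate_gpc(pexp, pts) - pts[, 1] * pts[, 2])), 1e-10)
  expect_equal(as.vector(evaluate_gpc(pexp, cbind(0.3, -0.7))), -0.21,
               tolerance = 1e-10)

  expect_error(fit_gpc(rep(1, 8), rule), "row-aligned")
  expect_warning(evaluate_gpc(pexp, cbind(1.5, 0)), "extrapolation")
})

test_that("gPC moments are exact and match Monte Carlo", {
  rule <- gl_rule(3, list(c(-1, 1)))
  e <- fit_gpc(sqrt(3) * rule$nodes[, 1], rule, p = 2)
  mom <- gpc_moments(e)
  expect_equal(as.vector(mom$mean), 0, tolerance = 1e-14)
  expect_equal(as.vector(mom$variance), 1, tolerance = 1e-12)

  cmod <- fit_gpc(rep(7, 3), rule, p = 2)
  expect_equal(as.vector(gpc_moments(cmod)$variance), 0)

  # variance from coefficients vs large-sample MC on the evaluated expansion
  f <- function(x) 1 + 0.4 * x + 0.7 * x^2
  e2 <- fit_gpc(f(rule$nodes[, 1]), rule, p = 2)
  set.seed(2)
  x <- runif(1e6, -1, 1)
  expect_equal(as.vector(gpc_moments(e2)$variance), var(f(x)),
               tolerance = 0.01)
})

test_that("complex observables fit identically to split real/imaginary fits", {
  rule <- gl_rule(3, list(c(0, 2), c(-1, 3)))
  set.seed(4)
  vals <- matrix(complex(real = rnorm(9 * 3), imaginary = rnorm(9 * 3)), 9, 3)
  joint <- fit_gpc(vals, rule, p = 2)
  re <- fit_gpc(Re(vals), rule, p = 2)
  im <- fit_gpc(Im(vals), rule, p = 2)
  expect_lt(max(Mod(joint$coefficients -
                      (re$coefficients + 1i * im$coefficients))), 1e-14)

  # Parseval on a polynomial input: quadrature norm equals coefficient norm
  f <- function(n) 2 + n[, 1] + 0.5 * n[, 1] * n[, 2]
  e <- fit_gpc(f(rule$nodes), rule, p = 2)
  quad_norm2 <- sum(f(rule$nodes)^2 * rule$weights)
  expect_equal(sum(Mod(e$coefficients)^2), quad_norm2, tolerance = 1e-12)
})
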