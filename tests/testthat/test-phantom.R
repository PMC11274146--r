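test_that("phantom labeling is concentric, clipped, and deterministic", {
  ph <- tiny_phantom()
  ctr <- (ph$grid_n + 1) / 2
  expect_equal(ph$labels[ctr, ctr, ctr], 1L)        # white-matter core
  expect_equal(ph$labels[1, 1, 1], 0L)              # corner is air
  r <- sqrt(rowSums(ph$coords^2))
  expect_true(all(r <= ph$radii[5] + 1e-12))        # tissue stays in the head
  expect_true(all(table(ph$label_t) > 0))           # all six tissues present

  ph2 <- build_head_phantom(grid_n = 15, voxel_size = 5,
                            radii = c(12, 18, 24, 28, 33),
                            eye_centers = rbind(c(8, 20, 0), c(-8, 20, 0)),
                            eye_radius = 5)
  expect_identical(ph2$labels, ph$labels)
  expect_error(build_head_phantom(grid_n = 11, voxel_size = 2,
                                  radii = c(5, 8, 10, 12, 30)),
               "exceed")
})

test_that("the constitutive relation gives the expected complex permittivity", {
  expect_equal(complex_permittivity(43.8, 0), complex(real = 8.8541878128e-12 * 43.8))
  e <- complex_permittivity(43.8, 0.413, 298.06e6)
  expect_equal(Re(e), 8.8541878128e-12 * 43.8)
  expect_equal(Im(e), -0.413 / (2 * pi * 2.9806e8))
  # loss term scales as 1/f
  e2 <- complex_permittivity(43.8, 0.413, 2 * 298.06e6)
  expect_equal(Im(e2), Im(e) / 2)
  expect_error(complex_permittivity(40, 0.4, -1))
})

test_that("the layered-sphere solver has the correct homogeneous and single-sphere limits", {
  radii <- c(12, 18, 24, 28, 33)
  eps0 <- 8.8541878128e-12 + 0i
  # all layers equal to the exterior: the applied field passes through unchanged
  sol <- solve_layered_sphere(rep(eps0, 5), radii, eps_exterior = eps0, e0 = 2)
  expect_lt(max(Mod(sol$B)) / radii[5]^3, 1e-12)
  expect_equal(sol$A, rep(complex(real = -2), 6), tolerance = 1e-12)

  # homogeneous dielectric sphere in air: classical interior-field factor
  e1 <- complex_permittivity(40, 0.4)
  sol2 <- solve_layered_sphere(rep(e1, 5), radii, e0 = 1)
  expect_equal(Mod(sol2$A[1]), Mod(3 * eps0 / (e1 + 2 * eps0)), tolerance = 1e-10)

  expect_error(solve_layered_sphere(rep(e1, 5), c(12, 12, 24, 28, 33)),
               "increasing")
})

test_that("interface continuity holds for random permittivities", {
  radii <- c(12, 18, 24, 28, 33)
  eps0 <- 8.8541878128e-12
  set.seed(12)
  for (rep in 1:5) {
    eps <- complex_permittivity(runif(5, 5, 80), runif(5, 0.05, 2.5))
    sol <- solve_layered_sphere(eps, radii, e0 = 1)
    all_eps <- c(eps, eps0 + 0i)
    for (l in 1:5) {
      rr <- radii[l]
      pot_in <- sol$A[l] * rr + sol$B[l] / rr^2
      pot_out <- sol$A[l + 1] * rr + sol$B[l + 1] / rr^2
      expect_lt(Mod(pot_in - pot_out) / Mod(pot_in), 1e-10)
      flx_in <- all_eps[l] * (sol$A[l] - 2 * sol$B[l] / rr^3)
      flx_out <- all_eps[l + 1] * (sol$A[l + 1] - 2 * sol$B[l + 1] / rr^3)
      expect_lt(Mod(flx_in - flx_out) / Mod(flx_in), 1e-10)
    }
  }
})

test_that("rendered fields vanish on air and respond to every input", {
  ph <- tiny_phantom()
  sp <- default_space()
  x <- reference_point(sp)
  fv <- render_efield(ph, x)
  air <- ph$labels == 0L
  expect_true(all(fv$Ex[air] == 0 & fv$Ey[air] == 0 & fv$Ez[air] == 0))
  expect_true(all(is.finite(Mod(fv$Ez))))

  # every one of the 12 dielectric inputs influences the output
  model <- phantom_model(ph, "efield")
  base <- model(x)
  for (k in 1:12) {
    xp <- x
    xp[k] <- xp[k] * 1.1
    expect_gt(max(Mod(model(xp) - base)), 0)
  }

  # perturbing bone conductivity couples into every shell, core included
  # (per-voxel change taken over all three field components: the core region
  # carries a purely axial field, so its transverse components are zero)
  xp <- x
  xp[10] <- xp[10] * 1.2
  nv <- ph$n_tissue
  dlt <- matrix(Mod(model(xp) - base), nv, 3)
  dmag <- sqrt(rowSums(dlt^2))
  for (shell in 1:5) {
    expect_gt(max(dmag[ph$shell_t == shell]), 0)
  }
})

test_that("fields are smooth in the inputs and carry genuine pair interactions", {
  ph <- tiny_phantom()
  sp <- default_space()
  x <- reference_point(sp)
  model <- phantom_model(ph, "sar", voxels = 1:50)
  # central differences stable under step halving
  for (k in c(1, 4, 10)) {
    h <- 0.02 * x[k]
    d1 <- (model(`[<-`(x, k, x[k] + h)) - model(`[<-`(x, k, x[k] - h))) / (2 * h)
    d2 <- (model(`[<-`(x, k, x[k] + h / 2)) -
             model(`[<-`(x, k, x[k] - h / 2))) / h
    expect_equal(max(abs(d1 / d2 - 1)), 0, tolerance = 0.01)
  }
  # nonzero mixed second difference: the adaptive scheme has pairs to find
  h4 <- function(si, sj) {
    xp <- x
    xp[4] <- x[4] * (1 + 0.1 * si)
    xp[11] <- x[11] * (1 + 0.1 * sj)
    model(xp)
  }
  mixed <- h4(1, 1) - h4(1, -1) - h4(-1, 1) + h4(-1, -1)
  expect_gt(max(abs(mixed)) / max(model(x)), 1e-6)
})

test_that("the nominal field solution matches its frozen regression values", {
  ph <- tiny_phantom()
  x <- reference_point(default_space())
  fv <- render_efield(ph, x)
  idx <- ph$tissue_index
  expect_equal(mean(Mod(fv$Ex[idx])), 9.482940664937e-03, tolerance = 1e-10)
  expect_equal(mean(Mod(fv$Ez[idx])), 5.497841253581e-02, tolerance = 1e-10)
  sarv <- phantom_model(ph, "sar")(x)
  expect_equal(sum(sarv), 1.602654377110e-03, tolerance = 1e-10)
  expect_equal(max(sarv), 2.854093318724e-06, tolerance = 1e-10)
})
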