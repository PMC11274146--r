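#' @importFrom stats median setNames quantile var
NULL

EPS0 <- 8.8541878128e-12   # vacuum permittivity, F/m
DEFAULT_FREQ <- 298.06e6   # 7 T proton Larmor frequency, Hz

#' Voxelized six-tissue layered-sphere head phantom
#'
#' A deterministic stand-in for a full-wave EM simulator: concentric
#' dielectric shells (white matter core, then grey matter, CSF, bone, scalp)
#' plus two eye-humor spheres embedded in the front of the head, discretized
#' on a cubic voxel grid.  Labels: 0 = air, 1..6 = white matter, grey matter,
#' CSF, bone, scalp, eye humor.
#'
#' @param grid_n Voxels per axis (odd keeps a voxel at the exact center).
#' @param voxel_size Edge length in mm.
#' @param radii Five strictly increasing shell radii in mm (white-matter core
#'   outward to scalp).
#' @param eye_centers 2 x 3 matrix of eye-sphere centers in mm ("front" is
#'   +y); eye voxels are clipped to the outermost shell radius so every
#'   tissue voxel stays inside the head.
#' @param eye_radius Eye-sphere radius in mm.
#' @param densities Tibble `label`, `tissue`, `density` (kg/m^3); defaults to
#'   the standard six-tissue table of [head_tissue_space()].
#' @return A `tissue_phantom`: grid geometry, the integer `labels` array, and
#'   precomputed tissue-voxel coordinates / shell indices used by the field
#'   solver.
#' @examples
#' ph <- build_head_phantom(grid_n = 25, voxel_size = 3.2)
#' table(ph$labels[ph$labels > 0])
#' @export
build_head_phantom <- function(grid_n = 49, voxel_size = 1.6,
                               radii = c(24, 28, 31, 35, 38),
                               eye_centers = rbind(c(12, 27.5, 0),
                                                   c(-12, 27.5, 0)),
                               eye_radius = 7,
                               densities = NULL) {
  stopifnot(length(radii) == 5, all(diff(radii) > 0))
  half_extent <- grid_n * voxel_size / 2
  if (radii[5] > half_extent) stop("radii exceed the grid extent")
  if (is.null(densities)) densities <- tissue_densities(head_tissue_space())

  ax <- (seq_len(grid_n) - (grid_n + 1) / 2) * voxel_size
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(coords^2))
  shell <- findInterval(r, radii, left.open = TRUE) + 1L  # 1..5 inside, 6 = air
  labels <- ifelse(shell <= 5L, shell, 0L)
  for (e in seq_len(nrow(eye_centers))) {
    d <- sqrt(colSums((t(coords) - eye_centers[e, ])^2))
    labels[d <= eye_radius & r <= radii[5]] <- 6L
  }
  tissue_index <- which(labels > 0L)
  if (length(tissue_index) == 0) stop("phantom has no tissue voxels")
  lab_arr <- array(labels, dim = c(grid_n, grid_n, grid_n))
  structure(
    list(
      grid_n = grid_n, voxel_size = voxel_size, radii = radii,
      eye_centers = eye_centers, eye_radius = eye_radius,
      labels = lab_arr, densities = densities,
      tissue_index = tissue_index,
      coords = coords[tissue_index, , drop = FALSE],
      label_t = labels[tissue_index],
      shell_t = pmin(shell[tissue_index], 5L),
      n_tissue = length(tissue_index)
    ),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", x$grid_n, "^3 grid, ", x$voxel_size, " mm voxels, ",
      x$n_tissue, " tissue voxels\n", sep = "")
  print(table(tissue = x$densities$tissue[x$label_t]))
  invisible(x)
}

#' Complex permittivity from relative permittivity and conductivity
#'
#' The standard constitutive relation
#' \eqn{\tilde\epsilon = \epsilon_0 \epsilon_r - i\,\sigma / (2\pi f)}.
#'
#' @param eps_r Relative permittivity (dimensionless).
#' @param sigma Conductivity in S/m.
#' @param freq Frequency in Hz (default 298.06 MHz, the 7 T Larmor
#'   frequency).
#' @return Complex permittivity in F/m.
#' @export
complex_permittivity <- function(eps_r, sigma, freq = DEFAULT_FREQ) {
  stopifnot(freq > 0)
  complex(real = EPS0 * eps_r, imaginary = -sigma / (2 * pi * freq))
}

#' Quasi-static potential coefficients of a five-layer dielectric sphere
#'
#' Solves the axisymmetric Laplace problem for concentric dielectric shells
#' in a uniform applied field \eqn{E_0 \hat z}: the potential in region
#' \eqn{l} is \eqn{(A_l r + B_l r^{-2})\cos\theta}, with continuity of the
#' potential and of \eqn{\tilde\epsilon\,\partial_r} potential at every
#' interface, \eqn{B = 0} in the core, and \eqn{-E_0 z} at infinity.
#'
#' @param eps_layers Five complex permittivities, innermost first.
#' @param radii Five strictly increasing interface radii (any consistent
#'   length unit; mm here).
#' @param eps_exterior Exterior permittivity (default vacuum/air).
#' @param e0 Applied field amplitude in V/m.
#' @return List with complex vectors `A`, `B` of length 6 (regions 1..5 and
#'   the exterior).
#' @export
solve_layered_sphere <- function(eps_layers, radii, eps_exterior = EPS0 + 0i,
                                 e0 = 1) {
  stopifnot(length(eps_layers) == 5, length(radii) == 5)
  if (any(eps_layers == 0) || eps_exterior == 0) stop("nonzero permittivities required")
  if (any(diff(radii) <= 0)) stop("invalid geometry: radii must be strictly increasing")
  # Nondimensionalize for conditioning: permittivities relative to the
  # exterior-independent scale EPS0, radii relative to the outer radius, and
  # B rescaled as C = B / R_out^3 (so all matrix entries are O(1..100)).
  eps <- c(as.complex(eps_layers), as.complex(eps_exterior)) / EPS0
  rn <- radii / radii[5]
  r_out3 <- 1  # in normalized radius units
  # unknowns: A1, (A2,C2), (A3,C3), (A4,C4), (A5,C5), C6
  acol <- function(l) if (l == 1L) 1L else 2L * l - 2L
  ccol <- function(l) 2L * l - 1L            # l in 2..5; C6 is column 10
  m <- matrix(0 + 0i, 10, 10)
  rhs <- rep(0 + 0i, 10)
  for (l in 1:5) {
    rr <- rn[l]
    row_pot <- 2L * l - 1L
    row_flx <- 2L * l
    m[row_pot, acol(l)] <- rr
    m[row_flx, acol(l)] <- eps[l]
    if (l > 1) {
      m[row_pot, ccol(l)] <- r_out3 / rr^2
      m[row_flx, ccol(l)] <- -2 * eps[l] * r_out3 / rr^3
    }
    if (l < 5) {
      m[row_pot, acol(l + 1L)] <- -rr
      m[row_pot, ccol(l + 1L)] <- -r_out3 / rr^2
      m[row_flx, acol(l + 1L)] <- -eps[l + 1L]
      m[row_flx, ccol(l + 1L)] <- 2 * eps[l + 1L] * r_out3 / rr^3
    } else {
      m[row_pot, 10L] <- -r_out3 / rr^2
      m[row_flx, 10L] <- 2 * eps[6L] * r_out3 / rr^3
      rhs[row_pot] <- -e0 * rr
      rhs[row_flx] <- -eps[6L] * e0
    }
  }
  u <- solve(m, rhs)
  # map back: B (in radii units cubed) = C * radii[5]^3
  b_scale <- radii[5]^3
  list(
    A = c(u[1], u[2], u[4], u[6], u[8], complex(real = -e0)),
    B = c(0 + 0i, u[3], u[5], u[7], u[9], u[10]) * b_scale
  )
}

# Layer permittivities (shells 1..5) and eye permittivity from the
# 12-dimensional input vector [eps_r 1..6, sigma 1..6].
layer_permittivities <- function(x, freq) {
  list(
    shells = complex_permittivity(x[1:5], x[7:11], freq),
    eye = complex_permittivity(x[6], x[12], freq)
  )
}

# Complex E-field components at selected tissue voxels for input vector x.
# Field applied along z; in region l,  E = (3B x z / r^5, 3B y z / r^5,
# -A - B/r^3 + 3B z^2 / r^5).  Eye voxels take the local background field of
# their underlying shell scaled by the embedded-sphere factor
# 3 eps_bg / (eps_eye + 2 eps_bg).
efield_at_voxels <- function(phantom, x, freq = DEFAULT_FREQ, e0 = 1,
                             idx = NULL) {
  perm <- layer_permittivities(x, freq)
  sol <- solve_layered_sphere(perm$shells, phantom$radii, e0 = e0)
  if (is.null(idx)) idx <- seq_len(phantom$n_tissue)
  co <- phantom$coords[idx, , drop = FALSE]
  shell <- phantom$shell_t[idx]
  lab <- phantom$label_t[idx]
  a <- sol$A[shell]
  b <- sol$B[shell]
  r2 <- rowSums(co^2)
  r5 <- r2^2 * sqrt(r2)
  r3 <- r2 * sqrt(r2)
  zz <- co[, 3]
  ex <- 3 * b * co[, 1] * zz / r5
  ey <- 3 * b * co[, 2] * zz / r5
  ez <- -a - b / r3 + 3 * b * zz^2 / r5
  at_origin <- r2 == 0
  if (any(at_origin)) {   # core: B = 0, field is uniform -A1 z-hat
    ex[at_origin] <- 0 + 0i
    ey[at_origin] <- 0 + 0i
    ez[at_origin] <- -sol$A[1]
  }
  is_eye <- lab == 6L
  if (any(is_eye)) {
    eps_bg <- perm$shells[shell[is_eye]]
    fac <- 3 * eps_bg / (perm$eye + 2 * eps_bg)
    ex[is_eye] <- ex[is_eye] * fac
    ey[is_eye] <- ey[is_eye] * fac
    ez[is_eye] <- ez[is_eye] * fac
  }
  cbind(Ex = ex, Ey = ey, Ez = ez)
}

#' Render the per-voxel complex E-field of the phantom
#'
#' Maps the 12 dielectric inputs to layer permittivities, solves the layered
#' sphere, and evaluates the analytic field at every tissue voxel center.
#' Air voxels carry exactly zero field.
#'
#' @param phantom A `tissue_phantom`.
#' @param x Input vector of length 12 in the frozen
#'   \eqn{[\epsilon_{r1..6}, \sigma_{1..6}]} order.
#' @param freq Frequency in Hz.
#' @param e0 Applied field amplitude, V/m.
#' @return A `field_volume`: complex arrays `Ex`, `Ey`, `Ez` on the grid plus
#'   `frequency`, `e0` and the grid geometry.
#' @export
render_efield <- function(phantom, x, freq = DEFAULT_FREQ, e0 = 1) {
  ef <- efield_at_voxels(phantom, x, freq, e0)
  dims <- dim(phantom$labels)
  mk <- function(col) {
    arr <- array(0 + 0i, dims)
    arr[phantom$tissue_index] <- col
    arr
  }
  structure(
    list(Ex = mk(ef[, 1]), Ey = mk(ef[, 2]), Ez = mk(ef[, 3]),
         frequency = freq, e0 = e0, voxel_size = phantom$voxel_size),
    class = "field_volume"
  )
}

#' Forward model closure over the phantom
#'
#' Packages the phantom solver as a deterministic map from the 12-dimensional
#' input vector to an observable vector, in either of the two modeling
#' conventions: `"sar"` (the direct approach: per-voxel SAR
#' \eqn{(|E_x|^2+|E_y|^2+|E_z|^2)\,\sigma_i/\rho_i}, the realized
#' conductivity of each voxel's tissue taken from the input vector) or
#' `"efield"` (the indirect approach: the complex field components,
#' concatenated `[Ex; Ey; Ez]` over tissue voxels, SAR to be assembled
#' afterwards).
#'
#' @param phantom A `tissue_phantom`.
#' @param output `"sar"` or `"efield"`.
#' @param freq Frequency in Hz.
#' @param e0 Applied field amplitude, V/m.
#' @param voxels Optional integer subset of tissue-voxel positions (indices
#'   into `phantom$tissue_index`) to restrict the observable to.
#' @return A function of the input vector, suitable for [build_hdmr()].
#' @export
phantom_model <- function(phantom, output = c("sar", "efield"),
                          freq = DEFAULT_FREQ, e0 = 1, voxels = NULL) {
  output <- match.arg(output)
  idx <- if (is.null(voxels)) seq_len(phantom$n_tissue) else voxels
  lab <- phantom$label_t[idx]
  rho <- phantom$densities$density[lab]
  force(freq); force(e0)
  function(x) {
    ef <- efield_at_voxels(phantom, x, freq, e0, idx)
    if (output == "efield") return(c(ef[, 1], ef[, 2], ef[, 3]))
    e2 <- Mod(ef[, 1])^2 + Mod(ef[, 2])^2 + Mod(ef[, 3])^2
    e2 * x[6 + lab] / rho
  }
}

#' Assemble SAR from a surrogate-predicted E-field vector
#'
#' Inverse of the indirect approach's field packing: given a matrix of
#' concatenated `[Ex; Ey; Ez]` predictions (rows = evaluation points) and the
#' corresponding input points, computes per-voxel SAR with the realized
#' conductivities.
#'
#' @param efields Complex matrix `n_points x 3*n_voxels`.
#' @param points Input points (rows aligned with `efields`).
#' @param phantom A `tissue_phantom`.
#' @param voxels Optional tissue-voxel subset matching the field packing.
#' @return Real matrix `n_points x n_voxels` of SAR in W/kg.
#' @export
sar_from_efields <- function(efields, points, phantom, voxels = NULL) {
  idx <- if (is.null(voxels)) seq_len(phantom$n_tissue) else voxels
  nv <- length(idx)
  stopifnot(ncol(efields) == 3 * nv)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  lab <- phantom$label_t[idx]
  rho <- phantom$densities$density[lab]
  e2 <- Mod(efields[, seq_len(nv), drop = FALSE])^2 +
    Mod(efields[, nv + seq_len(nv), drop = FALSE])^2 +
    Mod(efields[, 2 * nv + seq_len(nv), drop = FALSE])^2
  sig <- points[, 6 + lab, drop = FALSE]
  out <- e2 * sig * matrix(1 / rho, nrow(e2), nv, byrow = TRUE)
  dimnames(out) <- NULL
  out
}
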