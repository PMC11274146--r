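#' Per-voxel SAR from a field volume
#'
#' The point SAR of voxel i is
#' \eqn{(|E_{x,i}|^2 + |E_{y,i}|^2 + |E_{z,i}|^2)\,\sigma_i / \rho_i}
#' in W/kg, with \eqn{\sigma_i} looked up from the voxel's tissue label in
#' the supplied (realized) conductivity vector and \eqn{\rho_i} from the
#' tissue density table.  The formula is applied exactly as stated - no RMS
#' factor of 1/2; set `rms = TRUE` to adopt the peak-vs-RMS convention.
#'
#' @param field A `field_volume` (from [render_efield()]).
#' @param phantom The matching `tissue_phantom`.
#' @param sigma_per_tissue Conductivities (S/m) per tissue label 1..6,
#'   typically the \eqn{\sigma} half of the realized input vector.
#' @param rho_per_tissue Densities (kg/m^3) per label; defaults to the
#'   phantom's density table.
#' @param rms If `TRUE`, multiply by 1/2 (fields interpreted as peak values).
#' @return A `sar_volume`: real array of SAR values (zero on air), with the
#'   tissue mask and a `provenance` tag.
#' @export
voxel_sar <- function(field, phantom, sigma_per_tissue,
                      rho_per_tissue = NULL, rms = FALSE) {
  if (is.null(rho_per_tissue)) rho_per_tissue <- phantom$densities$density
  lab <- phantom$label_t
  if (max(lab) > length(sigma_per_tissue) || max(lab) > length(rho_per_tissue)) {
    stop("tissue label without a sigma/rho entry")
  }
  idx <- phantom$tissue_index
  e2 <- Mod(field$Ex[idx])^2 + Mod(field$Ey[idx])^2 + Mod(field$Ez[idx])^2
  vals <- e2 * sigma_per_tissue[lab] / rho_per_tissue[lab]
  if (rms) vals <- vals / 2
  new_sar_volume(vals, phantom, "direct_from_field")
}

#' Construct a SAR volume from per-tissue-voxel values
#'
#' @param values Numeric vector, one entry per tissue voxel (ordering of
#'   `phantom$tissue_index`).
#' @param phantom A `tissue_phantom`.
#' @param provenance Character tag (`"direct_surrogate"`,
#'   `"indirect_from_efield"`, `"ground_truth"`, ...).
#' @return A `sar_volume`.
#' @export
new_sar_volume <- function(values, phantom, provenance = "ground_truth") {
  stopifnot(length(values) == phantom$n_tissue)
  if (any(values < 0)) stop("SAR values must be nonnegative on tissue voxels")
  arr <- array(0, dim(phantom$labels))
  arr[phantom$tissue_index] <- values
  structure(
    list(values = arr, mask = phantom$labels > 0L, provenance = provenance,
         voxel_size = phantom$voxel_size),
    class = "sar_volume"
  )
}

#' @export
print.sar_volume <- function(x, ...) {
  v <- x$values[x$mask]
  cat("<sar_volume> (", x$provenance, ") ", sum(x$mask), " tissue voxels, ",
      "max ", signif(max(v), 4), " W/kg, mean ", signif(mean(v), 4),
      " W/kg\n", sep = "")
  invisible(x)
}

# 3-D inclusive prefix sums; boxsum() reads the sum over a clipped cube
# window in O(1) per voxel via inclusion-exclusion.
prefix_sum_3d <- function(arr) {
  d <- dim(arr)
  for (i in 2:d[1]) arr[i, , ] <- arr[i, , ] + arr[i - 1, , ]
  for (j in 2:d[2]) arr[, j, ] <- arr[, j, ] + arr[, j - 1, ]
  for (k in 2:d[3]) arr[, , k] <- arr[, , k] + arr[, , k - 1]
  arr
}

box_sums <- function(ps, lo, hi) {
  d <- dim(ps)
  at <- function(i, j, k) {
    ok <- i >= 1L & j >= 1L & k >= 1L
    out <- numeric(length(i))
    lin <- (k[ok] - 1L) * d[1] * d[2] + (j[ok] - 1L) * d[1] + i[ok]
    out[ok] <- ps[lin]
    out
  }
  at(hi[, 1], hi[, 2], hi[, 3]) -
    at(lo[, 1] - 1L, hi[, 2], hi[, 3]) -
    at(hi[, 1], lo[, 2] - 1L, hi[, 3]) -
    at(hi[, 1], hi[, 2], lo[, 3] - 1L) +
    at(lo[, 1] - 1L, lo[, 2] - 1L, hi[, 3]) +
    at(lo[, 1] - 1L, hi[, 2], lo[, 3] - 1L) +
    at(hi[, 1], lo[, 2] - 1L, lo[, 3] - 1L) -
    at(lo[, 1] - 1L, lo[, 2] - 1L, lo[, 3] - 1L)
}

#' Mass-averaged (1g / 10g) SAR
#'
#' For every tissue voxel, a cubic region of tissue-containing voxels is
#' grown around it one whole shell at a time (Chebyshev distance 0, 1, 2,
#' ...) until the accumulated tissue mass reaches the target; the assigned
#' value is the mass-weighted mean SAR over that region.  Air voxels
#' contribute neither mass nor SAR but do not block growth.  Voxels whose
#' region can never reach the target mass (phantom too small) are flagged
#' `NA` and reported in the `invalid` attribute rather than silently
#' dropped.
#'
#' @param sar A `sar_volume`.
#' @param phantom The matching `tissue_phantom`.
#' @param target_mass_g Target mass in grams (1 and 10 are the regulatory
#'   presets).
#' @param rho_per_tissue Densities per label; defaults to the phantom table.
#' @return A `sar_volume` of averaged values (`NA` on invalid voxels), with
#'   attributes `invalid` (logical per tissue voxel) and `region_radius`
#'   (the Chebyshev radius used at each voxel).
#' @export
mass_averaged_sar <- function(sar, phantom, target_mass_g,
                              rho_per_tissue = NULL) {
  stopifnot(target_mass_g > 0)
  if (is.null(rho_per_tissue)) rho_per_tissue <- phantom$densities$density
  target_kg <- target_mass_g / 1000
  vox_vol <- (phantom$voxel_size * 1e-3)^3                 # m^3
  d <- dim(phantom$labels)
  mass <- array(0, d)
  mass[phantom$tissue_index] <- vox_vol * rho_per_tissue[phantom$label_t]
  ps_mass <- prefix_sum_3d(mass)
  ps_msar <- prefix_sum_3d(mass * sar$values)

  ijk <- arrayInd(phantom$tissue_index, d)
  n <- nrow(ijk)
  value <- rep(NA_real_, n)
  radius <- rep(NA_integer_, n)
  pending <- seq_len(n)
  r <- 0L
  max_r <- max(d)
  while (length(pending) > 0 && r <= max_r) {
    sub <- ijk[pending, , drop = FALSE]
    lo <- pmax(sub - r, 1L)
    hi <- pmin(sub + r, matrix(d, length(pending), 3, byrow = TRUE))
    m <- box_sums(ps_mass, lo, hi)
    done <- m >= target_kg
    if (any(done)) {
      sel <- pending[done]
      value[sel] <- box_sums(ps_msar, lo[done, , drop = FALSE],
                             hi[done, , drop = FALSE]) / m[done]
      radius[sel] <- r
      pending <- pending[!done]
    }
    r <- r + 1L
  }
  invalid <- is.na(value)
  arr <- array(0, d)
  arr[phantom$tissue_index] <- value
  out <- structure(
    list(values = arr, mask = sar$mask,
         provenance = paste0(target_mass_g, "g_averaged"),
         voxel_size = sar$voxel_size),
    class = "sar_volume"
  )
  attr(out, "invalid") <- invalid
  attr(out, "region_radius") <- radius
  if (any(invalid)) {
    warning(sum(invalid), " voxel regions could not reach ", target_mass_g,
            " g within the grid; flagged NA")
  }
  out
}

#' Worst-case SAR estimate from per-voxel mean and variance
#'
#' Under the normality assumption for per-voxel SAR, the theoretical maximum
#' is estimated as mean + 3 standard deviations, elementwise.
#'
#' @param mean_sar A `sar_volume` (or numeric array) of means.
#' @param variance Numeric array of per-voxel variances (>= 0).
#' @return Object of the same class as `mean_sar`.
#' @export
max_sar_estimate <- function(mean_sar, variance) {
  if (any(variance < 0, na.rm = TRUE)) stop("negative variance input rejected")
  if (inherits(mean_sar, "sar_volume")) {
    mean_sar$values <- mean_sar$values + 3 * sqrt(variance)
    mean_sar$provenance <- paste0(mean_sar$provenance, "+3sd")
    mean_sar
  } else {
    mean_sar + 3 * sqrt(variance)
  }
}

#' Mask of the highest-SAR tissue voxels
#'
#' Selects the `ceiling(fraction * n_tissue)` tissue voxels with the highest
#' values (the "top 5%" plotting convention uses `fraction = 0.05`).
#'
#' @param sar A `sar_volume`.
#' @param fraction Fraction in (0, 1].
#' @return Logical array, `TRUE` on the selected voxels.
#' @export
top_fraction_mask <- function(sar, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- sar$values[sar$mask]
  k <- ceiling(fraction * length(v))
  cutoff <- sort(v, decreasing = TRUE)[k]
  out <- array(FALSE, dim(sar$values))
  sel <- which(sar$mask & sar$values >= cutoff)
  # resolve ties beyond k deterministically by index order
  if (length(sel) > k) sel <- sel[order(-sar$values[sel])][seq_len(k)]
  out[sel] <- TRUE
  out
}
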