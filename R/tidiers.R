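#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the component inventory of an HDMR surrogate
#'
#' One row per component function: its order, variable subset, importance
#' weight (first order), whether it entered the important set, the number of
#' new model evaluations it cost, and the total variance its gPC carries
#' (summed over outputs).
#'
#' @param x An `hdmr_surrogate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hdmr_surrogate <- function(x, ...) {
  comps <- c(list(NULL), x$first_order, x$second_order)
  ledger <- x$ledger
  var_tot <- vapply(comps, function(comp) {
    if (is.null(comp)) return(0)
    sum(gpc_moments(comp)$variance)
  }, numeric(1))
  ord1 <- ledger$order == 1
  eta <- rep(NA_real_, nrow(ledger))
  eta[ord1] <- x$eta[as.integer(ledger$subset[ord1])]
  important <- rep(NA, nrow(ledger))
  important[ord1] <- as.integer(ledger$subset[ord1]) %in% x$important
  dplyr::mutate(ledger, eta = eta, important = important,
                total_variance = var_tot)
}

#' @rdname tidy.hdmr_surrogate
#' @export
glance.hdmr_surrogate <- function(x, ...) {
  tibble::tibble(
    n_dims = length(x$first_order),
    n_important = length(x$important),
    n_pairs = length(x$second_order),
    p = x$p, n_gl = x$n_gl, tol = x$tol, max_order = x$max_order,
    n_outputs = x$n_outputs,
    ncp = attr(x$ledger, "total")
  )
}

#' Tidy a Monte Carlo convergence trace / summary
#'
#' `tidy()` returns the checkpointed convergence trace (one row per
#' checkpoint and traced output); `glance()` the one-row run summary.
#'
#' @param x An `mc_statistics`.
#' @param ... Unused.
#' @export
tidy.mc_statistics <- function(x, ...) x$trace

#' @rdname tidy.mc_statistics
#' @export
glance.mc_statistics <- function(x, ...) {
  tibble::tibble(
    n = x$n, seed = x$seed, n_outputs = length(x$mean),
    mean_of_means = mean(Mod(x$mean)), mean_variance = mean(x$variance)
  )
}

#' Tidy a surrogate validation error report
#'
#' `tidy()` gives per-voxel relative errors; `glance()` the scalar summary
#' (average and guarded-maximum relative error, exceedance fraction).
#'
#' @param x An `error_report`.
#' @param ... Unused.
#' @export
tidy.error_report <- function(x, ...) {
  tibble::tibble(
    voxel = seq_along(x$per_voxel),
    err = x$per_voxel,
    guarded_out = seq_along(x$per_voxel) %in% x$excluded
  )
}

#' @rdname tidy.error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble::tibble(
    err_ave = x$err_ave, err_ave_guarded = x$err_ave_guarded,
    err_max = x$err_max, threshold = x$threshold,
    threshold_exceedance = x$threshold_exceedance,
    n_test = x$n_test, n_voxels = x$n_voxels, n_excluded = length(x$excluded)
  )
}

#' Tidy cut-based Sobol indices into long format
#'
#' @param x A `sobol_cut` matrix.
#' @param ... Unused.
#' @return Tibble with columns `input`, `output`, `sobol`.
#' @export
tidy.sobol_cut <- function(x, ...) {
  m <- unclass(x)
  attr(m, "full_variance") <- NULL
  attr(m, "n") <- NULL
  tibble::tibble(
    input = rep(rownames(m), ncol(m)),
    output = rep(seq_len(ncol(m)), each = nrow(m)),
    sobol = as.vector(m)
  )
}

#' @rdname tidy.hdmr_surrogate
#' @export
tidy.ls_gpc <- function(x, ...) {
  tibble::tibble(
    term = apply(x$basis, 1, paste, collapse = ","),
    degree = rowSums(x$basis),
    coef_norm = sqrt(rowSums(Mod(x$coefficients)^2))
  )
}

#' @rdname tidy.hdmr_surrogate
#' @export
glance.ls_gpc <- function(x, ...) {
  tibble::tibble(
    degree = x$degree, n_terms = nrow(x$basis), n_train = x$n_train,
    residual_norm = x$residual_norm, n_outputs = ncol(x$coefficients)
  )
}
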