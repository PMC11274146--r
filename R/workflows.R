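#' Build an HDMR surrogate of the phantom per a run configuration
#'
#' The direct approach builds the surrogate on per-voxel SAR; the indirect
#' approach on the complex E-field components (output length three times the
#' tissue-voxel count), with SAR assembled afterwards by [sar_evaluator()].
#' The collocation ledger and realized important set are attached to the
#' returned surrogate and, when `out_dir` is set, the surrogate container and
#' a build log are written there.
#'
#' @param config A `run_config`.
#' @param phantom Optional prebuilt `tissue_phantom` (otherwise built from
#'   the config geometry).
#' @param voxels Optional tissue-voxel subset to restrict the observable.
#' @return The `hdmr_surrogate`, with the phantom attached as attribute
#'   `phantom`.
#' @export
run_build <- function(config, phantom = NULL, voxels = NULL) {
  config <- validate_run_config(config)
  if (is.null(phantom)) {
    phantom <- build_head_phantom(grid_n = config$grid_n,
                                  voxel_size = config$voxel_size,
                                  radii = config$radii)
  }
  space <- head_tissue_space()
  model <- phantom_model(
    phantom,
    output = if (config$approach == "direct") "sar" else "efield",
    voxels = voxels
  )
  surrogate <- build_hdmr(model, space, p = config$p, n_gl = config$n_gl,
                          tol = config$tol, max_order = config$max_order)
  attr(surrogate, "phantom") <- phantom
  attr(surrogate, "approach") <- config$approach
  attr(surrogate, "voxels") <- voxels
  if (!is.null(config$out_dir)) {
    save_surrogate(surrogate, file.path(config$out_dir, "surrogate"))
    jsonlite::write_json(
      list(approach = config$approach, ncp = attr(surrogate$ledger, "total"),
           important = surrogate$important, eta = surrogate$eta),
      file.path(config$out_dir, "build_log.json"),
      digits = NA, auto_unbox = TRUE
    )
  }
  surrogate
}

#' SAR-valued evaluator from a surrogate
#'
#' Wraps a built surrogate as a batched evaluator returning per-voxel SAR.
#' For a direct-approach surrogate this is plain evaluation; for an
#' indirect-approach surrogate the predicted complex fields are converted
#' voxel-wise with the realized conductivities of each evaluation point.
#'
#' @param surrogate An `hdmr_surrogate` built by [run_build()] (or any
#'   surrogate with the same attributes attached).
#' @param phantom The phantom (default: the one attached to the surrogate).
#' @return A batched evaluator `(points, outputs = NULL) -> matrix` of SAR
#'   values, accepted directly by [mc_statistics()] and [sobol_cut()].
#' @export
sar_evaluator <- function(surrogate, phantom = attr(surrogate, "phantom")) {
  approach <- attr(surrogate, "approach")
  voxels <- attr(surrogate, "voxels")
  if (is.null(approach)) approach <- if (surrogate$complex_output) "indirect" else "direct"
  f <- if (approach == "direct") {
    function(points, outputs = NULL) evaluate_hdmr(surrogate, points, outputs)
  } else {
    nv <- surrogate$n_outputs / 3
    function(points, outputs = NULL) {
      if (is.null(dim(points))) points <- matrix(points, nrow = 1)
      cols <- if (is.null(outputs)) NULL else c(outputs, nv + outputs, 2 * nv + outputs)
      ef <- evaluate_hdmr(surrogate, points, cols)
      vox <- if (is.null(voxels)) seq_len(phantom$n_tissue) else voxels
      if (!is.null(outputs)) vox <- vox[outputs]
      sar_from_efields(ef, points, phantom, vox)
    }
  }
  structure(f, class = c("batched_evaluator", "function"))
}

#' Full statistics bundle from a built surrogate
#'
#' Runs the surrogate-assisted Monte Carlo analysis surface: per-voxel SAR
#' mean and variance, the worst-case (mean + 3 sd) map, nominal and
#' worst-case 1g/10g mass-averaged SAR, top-5% masks, per-tissue cut-Sobol
#' indices and the convergence trace.  When `config$out_dir` is set, maps are
#' written as NIfTI and tables as CSV.
#'
#' @param config A `run_config`.
#' @param surrogate A surrogate from [run_build()] (covering all tissue
#'   voxels).
#' @param n_sobol MC sample size per Sobol cut (default `config$n_mc`;
#'   reduce for large voxel counts).
#' @param sobol_voxels Optional voxel subset for the Sobol maps.
#' @return List with `mc` (`mc_statistics`), `nominal_sar`, `mean_sar`,
#'   `max_sar`, `sar_1g`, `sar_10g`, `max_sar_1g`, `max_sar_10g`,
#'   `top5_mask`, `sobol` (per-voxel `sobol_cut`), `sobol_tissue` (tibble).
#' @export
run_report <- function(config, surrogate, n_sobol = NULL,
                       sobol_voxels = NULL) {
  config <- validate_run_config(config)
  phantom <- attr(surrogate, "phantom")
  ev <- sar_evaluator(surrogate, phantom)

  mc <- mc_statistics(ev, surrogate$space, n = config$n_mc,
                      seed = config$seed, trace_outputs = integer(0))
  nominal_vec <- as.vector(ev(matrix(reference_point(surrogate$space), 1)))
  nominal_sar <- new_sar_volume(nominal_vec, phantom, "nominal")
  mean_sar <- new_sar_volume(mc$mean, phantom, "mc_mean")
  var_arr <- array(0, dim(phantom$labels))
  var_arr[phantom$tissue_index] <- mc$variance
  max_sar <- max_sar_estimate(mean_sar, var_arr)
  max_sar$provenance <- "mean+3sd"

  sar_1g <- mass_averaged_sar(nominal_sar, phantom, 1)
  sar_10g <- mass_averaged_sar(nominal_sar, phantom, 10)
  max_sar_1g <- mass_averaged_sar(max_sar, phantom, 1)
  max_sar_10g <- mass_averaged_sar(max_sar, phantom, 10)
  top5 <- top_fraction_mask(max_sar, 0.05)

  if (is.null(n_sobol)) n_sobol <- config$n_mc
  sob <- sobol_cut(ev, surrogate$space, n = n_sobol, seed = config$seed,
                   outputs = sobol_voxels)
  lab <- phantom$label_t
  if (!is.null(sobol_voxels)) lab <- lab[sobol_voxels]
  sob_tissue <- tissue_averaged_sobol(sob, lab,
                                      tissue_names = phantom$densities$tissue)

  out <- list(mc = mc, nominal_sar = nominal_sar, mean_sar = mean_sar,
              max_sar = max_sar, sar_1g = sar_1g, sar_10g = sar_10g,
              max_sar_1g = max_sar_1g, max_sar_10g = max_sar_10g,
              top5_mask = top5, sobol = sob, sobol_tissue = sob_tissue)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    vx <- phantom$voxel_size
    write_volume(mean_sar$values, file.path(config$out_dir, "sar_mean.nii.gz"), vx)
    write_volume(var_arr, file.path(config$out_dir, "sar_variance.nii.gz"), vx)
    write_volume(max_sar$values, file.path(config$out_dir, "sar_max.nii.gz"), vx)
    write_volume(sar_1g$values, file.path(config$out_dir, "sar_1g.nii.gz"), vx)
    write_volume(sar_10g$values, file.path(config$out_dir, "sar_10g.nii.gz"), vx)
    readr::write_csv(sob_tissue, file.path(config$out_dir, "sobol_tissue.csv"))
    readr::write_csv(mc$trace, file.path(config$out_dir, "mc_trace.csv"))
  }
  out
}

#' Validate a surrogate against brute-force phantom evaluations
#'
#' Draws `n_test` uniform test points, evaluates the phantom exactly and the
#' surrogate approximately, and reports the per-voxel relative-error
#' summary - always on SAR values, whichever approach built the surrogate.
#'
#' @param surrogate A surrogate from [run_build()].
#' @param config A `run_config` (supplies `n_test` and the seed).
#' @param phantom The phantom (default: attached).
#' @return An `error_report`.
#' @export
run_validate <- function(surrogate, config, phantom = attr(surrogate, "phantom")) {
  config <- validate_run_config(config)
  space <- surrogate$space
  test <- sample_uniform(space, config$n_test,
                         seed = child_seed(config$seed, "test"))
  pts <- design_matrix(test)
  voxels <- attr(surrogate, "voxels")
  truth_model <- phantom_model(phantom, output = "sar", voxels = voxels)
  truth <- do.call(rbind, lapply(seq_len(nrow(pts)),
                                 function(r) truth_model(pts[r, ])))
  pred <- sar_evaluator(surrogate, phantom)(pts)
  relative_error_report(truth, pred)
}
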