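# JSON stores doubles at ~15 significant digits; fields whose round trip must
# be bit-exact are written as %.17g strings (17 significant digits uniquely
# identify a double) and re-parsed with as.numeric().
fmt_dbl <- function(x) sprintf("%.17g", x)

#' Write / read a voxel volume as NIfTI
#'
#' Volumes are written with an isotropic `voxel_size`-scaled affine so every
#' map the package emits (labels, SAR, statistics, Sobol maps) round-trips
#' through standard neuroimaging tooling.
#'
#' @param arr Numeric (or integer) 3-D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Edge length in mm.
#' @return `write_volume` returns `path` invisibly; `read_volume` the array
#'   with attribute `voxel_size`.
#' @export
write_volume <- function(arr, path, voxel_size = 1.6) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(voxel_size, 3)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  out <- as.array(im)
  attr(out, "voxel_size") <- RNifti::pixdim(im)[1]
  out
}

#' Write / read a complex field volume as paired real/imaginary NIfTI files
#'
#' Each component is stored as `<stem>_<comp>_real.nii.gz` and
#' `<stem>_<comp>_imag.nii.gz`.
#'
#' @param field A `field_volume`.
#' @param stem Path stem (no extension).
#' @return `write_field_volume` returns the stem invisibly;
#'   `read_field_volume` the reconstructed `field_volume`.
#' @export
write_field_volume <- function(field, stem) {
  for (comp in c("Ex", "Ey", "Ez")) {
    write_volume(Re(field[[comp]]), paste0(stem, "_", comp, "_real.nii.gz"),
                 field$voxel_size)
    write_volume(Im(field[[comp]]), paste0(stem, "_", comp, "_imag.nii.gz"),
                 field$voxel_size)
  }
  invisible(stem)
}

#' @rdname write_field_volume
#' @param frequency Frequency in Hz recorded on the reconstructed object.
#' @export
read_field_volume <- function(stem, frequency = DEFAULT_FREQ) {
  rd <- function(comp, part) {
    read_volume(paste0(stem, "_", comp, "_", part, ".nii.gz"))
  }
  mk <- function(comp) {
    re <- rd(comp, "real")
    array(complex(real = re, imaginary = rd(comp, "imag")), dim(re))
  }
  vx <- attr(rd("Ex", "real"), "voxel_size")
  structure(
    list(Ex = mk("Ex"), Ey = mk("Ey"), Ez = mk("Ez"),
         frequency = frequency, e0 = NA_real_, voxel_size = vx),
    class = "field_volume"
  )
}

#' Serialize an HDMR surrogate to a hierarchical on-disk container
#'
#' The surrogate is written as a directory: `manifest.json` (build settings,
#' importance weights, important set, parameter space, ledger) plus one CSV
#' per component function holding the multi-index block and the coefficient
#' matrix (`re_*` / `im_*` columns).  Everything round-trips to full double
#' precision.
#'
#' @param surrogate An `hdmr_surrogate`.
#' @param dir Target directory (created if missing).
#' @return `save_surrogate` returns `dir` invisibly; `load_surrogate` the
#'   reconstructed surrogate.
#' @export
save_surrogate <- function(surrogate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp_table <- function(comp) {
    cf <- comp$coefficients
    out <- as.data.frame(comp$basis)
    names(out) <- paste0("deg", seq_len(ncol(comp$basis)))
    re <- as.data.frame(Re(cf)); names(re) <- paste0("re_", seq_len(ncol(cf)))
    out <- cbind(out, re)
    if (is.complex(cf)) {
      im <- as.data.frame(Im(cf)); names(im) <- paste0("im_", seq_len(ncol(cf)))
      out <- cbind(out, im)
    }
    out
  }
  for (i in seq_along(surrogate$first_order)) {
    readr::write_csv(comp_table(surrogate$first_order[[i]]),
                     file.path(dir, sprintf("first_%02d.csv", i)))
  }
  for (nm in names(surrogate$second_order)) {
    readr::write_csv(comp_table(surrogate$second_order[[nm]]),
                     file.path(dir, paste0("pair_", gsub(",", "_", nm), ".csv")))
  }
  f0 <- surrogate$f0
  readr::write_csv(
    tibble::tibble(re = Re(f0), im = if (is.complex(f0)) Im(f0) else 0),
    file.path(dir, "f0.csv")
  )
  manifest <- list(
    p = surrogate$p, n_gl = surrogate$n_gl, tol = surrogate$tol,
    max_order = surrogate$max_order, weight = surrogate$weight,
    n_outputs = surrogate$n_outputs, complex_output = surrogate$complex_output,
    eta = fmt_dbl(surrogate$eta), important = surrogate$important,
    pairs = names(surrogate$second_order),
    ledger = as.data.frame(surrogate$ledger),
    ledger_total = attr(surrogate$ledger, "total")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  write_param_space(surrogate$space, file.path(dir, "space.json"))
  readr::write_csv(
    tibble::as_tibble(as.data.frame(attr(surrogate$ledger, "unique_points"))),
    file.path(dir, "collocation_points.csv")
  )
  invisible(dir)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  space <- read_param_space(file.path(dir, "space.json"))
  box <- param_box(space)
  ref <- reference_point(space)
  read_comp <- function(path, subset) {
    tb <- readr::read_csv(path, show_col_types = FALSE)
    nd <- length(subset)
    basis <- as.matrix(tb[, seq_len(nd), drop = FALSE])
    dimnames(basis) <- NULL
    storage.mode(basis) <- "integer"
    re <- as.matrix(tb[, grepl("^re_", names(tb)), drop = FALSE])
    im_cols <- grepl("^im_", names(tb))
    cf <- if (any(im_cols)) re + 1i * as.matrix(tb[, im_cols, drop = FALSE]) else re
    dimnames(cf) <- NULL
    structure(
      list(coefficients = cf, basis = basis,
           box = box[subset, , drop = FALSE], center = ref[subset],
           subset = subset, degree = max(rowSums(basis))),
      class = "gpc_expansion"
    )
  }
  n_dims <- nrow(box)
  first_order <- lapply(seq_len(n_dims), function(i) {
    read_comp(file.path(dir, sprintf("first_%02d.csv", i)), i)
  })
  pairs <- manifest$pairs
  second_order <- list()
  for (nm in pairs) {
    subset <- as.integer(strsplit(nm, ",", fixed = TRUE)[[1]])
    second_order[[nm]] <-
      read_comp(file.path(dir, paste0("pair_", gsub(",", "_", nm), ".csv")), subset)
  }
  f0_tb <- readr::read_csv(file.path(dir, "f0.csv"), show_col_types = FALSE)
  f0 <- if (isTRUE(manifest$complex_output)) {
    complex(real = f0_tb$re, imaginary = f0_tb$im)
  } else {
    f0_tb$re
  }
  pts <- as.matrix(readr::read_csv(file.path(dir, "collocation_points.csv"),
                                   show_col_types = FALSE))
  ledger <- tibble::as_tibble(manifest$ledger)
  structure(
    list(space = space, f0 = f0, first_order = first_order,
         second_order = second_order, eta = as.numeric(manifest$eta),
         important = as.integer(manifest$important), tol = manifest$tol,
         p = manifest$p,
         n_gl = manifest$n_gl, max_order = manifest$max_order,
         weight = manifest$weight, n_outputs = manifest$n_outputs,
         complex_output = isTRUE(manifest$complex_output),
         ledger = structure(ledger, unique_points = pts,
                            total = manifest$ledger_total)),
    class = "hdmr_surrogate"
  )
}

#' Run configuration for the two end-to-end workflows
#'
#' Collects every knob of a build-and-report run: the modeling approach
#' (`"direct"` surrogate over SAR, or `"indirect"` over complex E-field
#' components with SAR assembled afterwards), the gPC/HDMR settings, the
#' phantom geometry, sample sizes and seeds.
#'
#' @param approach `"indirect"` (default) or `"direct"`.
#' @param p Total gPC degree (default 2).
#' @param n_gl Gauss-Legendre points per dimension; one of 3, 5, 7.
#' @param tol Importance tolerance (default 1e-2).
#' @param max_order HDMR truncation order, 1 or 2 (default 2).
#' @param grid_n,voxel_size,radii Phantom geometry (see
#'   [build_head_phantom()]).
#' @param seed Master seed.
#' @param n_mc Surrogate-assisted MC sample size (default 10,000).
#' @param n_test Validation test points (default 100).
#' @param out_dir Output directory (default: none, nothing written).
#' @return A validated `run_config` list.
#' @export
run_config <- function(approach = c("indirect", "direct"), p = 2, n_gl = 3,
                       tol = 1e-2, max_order = 2, grid_n = 49,
                       voxel_size = 1.6, radii = c(24, 28, 31, 35, 38),
                       seed = 1L, n_mc = 10000, n_test = 100,
                       out_dir = NULL) {
  cfg <- list(approach = match.arg(approach), p = p, n_gl = n_gl, tol = tol,
              max_order = max_order, grid_n = grid_n, voxel_size = voxel_size,
              radii = radii, seed = seed, n_mc = n_mc, n_test = n_test,
              out_dir = out_dir)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  flag <- function(cond, msg) if (cond) problems <<- c(problems, msg)
  flag(!cfg$approach %in% c("direct", "indirect"),
       "approach must be 'direct' or 'indirect'")
  flag(!cfg$n_gl %in% c(3, 5, 7), "n_gl must be one of 3, 5, 7")
  flag(cfg$n_gl %% 2 == 0, "n_gl must be odd")
  flag(cfg$p < 1, "p must be >= 1")
  flag(!cfg$max_order %in% c(1, 2), "max_order must be 1 or 2")
  flag(cfg$n_mc < 2, "n_mc must be >= 2")
  flag(cfg$n_test < 1, "n_test must be >= 1")
  flag(length(cfg$radii) != 5 || any(diff(cfg$radii) <= 0),
       "radii must be five increasing lengths")
  if (length(problems) > 0) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Missing fields take the [run_config()] defaults; validation failures are
#' listed exhaustively.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("invalid run configuration:\n  - unknown fields: ",
         paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}
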