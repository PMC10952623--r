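## End-to-end commands chaining simulation, waveform analysis, fitting, and
## reporting, plus a thin command-line dispatcher. All commands are
## deterministic for a given seed and write a provenance JSON next to their
## outputs. Exit codes: 0 success, 2 validation error, 1 runtime error.

write_provenance <- function(dir, command, args) {
  prov <- list(command = command, package = "cardioqti",
               version = as.character(packageVersion("cardioqti")),
               args = args)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_outdir <- function(dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop_validation("output directory ", dir,
                    " is not empty; use force = TRUE to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir
}

#' Characterize gradient waveform files
#'
#' For each file: b-value and b-tensor shape, moment magnitudes m0..m3,
#' mean and peak spectral frequency, Maxwell index, peak amplitude and slew
#' rate vs limits, and the motion-compensation verdict. Files are taken in
#' laboratory polarity unless flagged effective in their header; the
#' Maxwell index is only defined for laboratory polarity.
#'
#' @param paths character vector of waveform file paths.
#' @param dt,gmax forwarded to [load_waveform()].
#' @param compensation_order order required for the compensation verdict.
#' @param amplitude_limit,slew_limit hardware limits (T/m, T/m/s).
#' @param out optional path of a JSON report to write.
#' @return (invisibly) a list of per-waveform reports.
#' @export
cmd_waveform_info <- function(paths, dt = NULL, gmax = NULL,
                              compensation_order = 2L,
                              amplitude_limit = 0.080, slew_limit = 100,
                              out = NULL) {
  if (!length(paths)) stop_validation("no waveform files given")
  reports <- lapply(paths, function(p) {
    if (!file.exists(p)) stop_validation("waveform file not found: ", p)
    w <- load_waveform(p, dt = dt, gmax = gmax)
    mx <- if (w$stored_as_effective) NA_real_ else maxwell_index(w)
    eff <- if (w$stored_as_effective) w else effective_waveform(w)
    B <- btensor_of_waveform(eff)
    ms <- moments(eff, 3L)
    sp <- encoding_spectrum(eff)
    sl <- slew_and_amplitude(w, amplitude_limit, slew_limit)
    comp <- validate_motion_compensation(eff, compensation_order)
    list(file = p,
         b_ms_um2 = B$b, b_delta = B$b_delta,
         moment_magnitudes = as.list(ms$magnitudes),
         mean_frequency_Hz = sp$mean_frequency,
         peak_frequency_Hz = sp$peak_frequency,
         maxwell_index_mT2_ms = mx,
         amplitude_mT_m = sl$amplitude_mT_m,
         slew_T_m_s = sl$slew_T_m_s,
         amplitude_ok = sl$amplitude_ok, slew_ok = sl$slew_ok,
         compensation_order_required = compensation_order,
         compensation_pass = comp$pass)
  })
  names(reports) <- basename(paths)
  if (!is.null(out))
    jsonlite::write_json(reports, out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(reports)
}

#' Build and write an acquisition protocol
#'
#' @param out scheme file path.
#' @param shells,rotations,shapes,seed forwarded to [build_protocol()].
#' @return (invisibly) the scheme.
#' @export
cmd_protocol <- function(out, shells = c(0.1, 0.4, 0.7, 1.1, 1.5),
                         rotations = c(10, 20, 30, 40, 50),
                         shapes = c("LTE", "PTE"), seed = 1L) {
  scheme <- build_protocol(shells, rotations, shapes, seed)
  if (length(shapes) < 2 || length(shells) < 2)
    warning("single-shape or single-shell design: the covariance fit will ",
            "not be identifiable from this scheme")
  write_scheme(scheme, out)
  message(sprintf("wrote %d volumes (%s; shells %s) to %s",
                  scheme_length(scheme), paste(shapes, collapse = "+"),
                  paste(shells, collapse = ", "), out))
  invisible(scheme)
}

#' Simulate a phantom dataset on disk
#'
#' Writes the 4D signal volume, the scheme, per-metric ground-truth maps,
#' and a provenance JSON. Deterministic for a given seed.
#'
#' @param out_dir output directory.
#' @param phantom `"two-block"` or `"ventricle"`.
#' @param angle_deg interblock angle (two-block phantom).
#' @param grid voxel grid.
#' @param d_par,d_perp phantom component diffusivities (um^2/ms).
#' @param shells,rotations,shapes,seed protocol design.
#' @param snr optional Rician SNR; `NULL` for noiseless data.
#' @param s0 baseline signal.
#' @param force overwrite a non-empty output directory.
#' @return (invisibly) the `synthetic_dataset`.
#' @export
cmd_simulate <- function(out_dir, phantom = c("two-block", "ventricle"),
                         angle_deg = 45, grid = NULL,
                         d_par = 2.0, d_perp = 0.6,
                         shells = c(0.1, 0.4, 0.7, 1.1, 1.5) * 0.3,
                         rotations = c(10, 20, 30, 40, 50),
                         shapes = c("LTE", "PTE"), seed = 1L,
                         snr = NULL, s0 = 1, force = FALSE) {
  phantom <- match.arg(phantom)
  spec <- switch(phantom,
    "two-block" = two_block_phantom(angle_deg, d_par = d_par,
                                    d_perp = d_perp,
                                    grid = if (is.null(grid)) c(6, 6, 3)
                                           else grid),
    "ventricle" = ventricle_fixture(grid = if (is.null(grid)) c(24, 24, 1)
                                           else grid,
                                    d_par = d_par, d_perp = d_perp))
  scheme <- build_protocol(shells, rotations, shapes, seed)
  ds <- synthesize_signals(spec, scheme, s0 = s0)
  if (!is.null(snr)) ds <- add_rician_noise(ds, snr, seed = seed)
  ensure_outdir(out_dir, force)
  RNifti::writeNifti(ds$signals, file.path(out_dir, "signals.nii.gz"))
  write_scheme(scheme, file.path(out_dir, "scheme.tsv"))
  for (m in qti_metric_names())
    RNifti::writeNifti(ds$truth[[m]],
                       file.path(out_dir, sprintf("truth_%s.nii.gz", m)))
  RNifti::writeNifti(array(as.numeric(spec$labels != 0), spec$grid),
                     file.path(out_dir, "mask.nii.gz"))
  write_provenance(out_dir, "simulate",
                   list(phantom = phantom, angle_deg = angle_deg,
                        grid = spec$grid, d_par = d_par, d_perp = d_perp,
                        shells = shells,
                        rotations = rotations, shapes = shapes,
                        seed = seed, snr = snr, s0 = s0))
  invisible(ds)
}

#' Fit the covariance model voxelwise and write metric maps
#'
#' @param volumes path to a 4D NIfTI of signals.
#' @param scheme path to the matching scheme file.
#' @param out_dir output directory.
#' @param mask optional path to a 3D NIfTI mask (nonzero = fit); without a
#'   mask the whole volume is fitted with a warning.
#' @param rois optional path to an integer ROI label map for the ROI table.
#' @param force overwrite a non-empty output directory.
#' @return (invisibly) a list of metric arrays.
#' @export
cmd_fit <- function(volumes, scheme, out_dir, mask = NULL, rois = NULL,
                    force = FALSE) {
  for (p in c(volumes, scheme, mask, rois))
    if (!file.exists(p)) stop_validation("input file not found: ", p)
  img <- RNifti::readNifti(volumes)
  sch <- read_scheme(scheme)
  dims <- dim(img)
  if (length(dims) != 4)
    stop_validation("expected a 4D volume, got dimensions ",
                    paste(dims, collapse = "x"))
  if (dims[4] != scheme_length(sch))
    stop_validation("volume count mismatch: image has ", dims[4],
                    " volumes, scheme lists ", scheme_length(sch))
  sel <- if (!is.null(mask)) {
    m <- RNifti::readNifti(mask)
    array(m != 0, dims[1:3])
  } else {
    warning("no mask given: fitting the whole volume")
    array(TRUE, dims[1:3])
  }
  maps <- lapply(c(qti_metric_names(), "S0"),
                 function(m) array(NaN, dims[1:3]))
  names(maps) <- c(qti_metric_names(), "S0")
  idx <- which(sel, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    s <- img[idx[k, 1], idx[k, 2], idx[k, 3], ]
    met <- tryCatch({
      cf <- fit_qti(as.numeric(s), sch)
      c(metrics_from_coefficients(cf), list(S0 = cf$s0))
    }, error = function(e) NULL)
    if (is.null(met)) next
    for (m in names(maps))
      maps[[m]][idx[k, 1], idx[k, 2], idx[k, 3]] <- met[[m]]
  }
  ensure_outdir(out_dir, force)
  for (m in names(maps))
    RNifti::writeNifti(maps[[m]], file.path(out_dir,
                                            sprintf("%s.nii.gz", m)))
  roi_map <- if (!is.null(rois)) {
    array(as.integer(RNifti::readNifti(rois)), dims[1:3])
  } else {
    array(as.integer(sel), dims[1:3])
  }
  tabs <- lapply(qti_metric_names(), function(m) {
    st <- roi_stats(maps[[m]], roi_map)
    st$metric <- m
    st
  })
  tab <- do.call(rbind, tabs)[, c("metric", "roi", "mean", "sd", "n")]
  write.table(tab, file.path(out_dir, "roi_stats.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write_provenance(out_dir, "fit",
                   list(volumes = volumes, scheme = scheme, mask = mask,
                        rois = rois))
  invisible(maps)
}

#' Bland-Altman repeatability between two fitted runs
#'
#' @param dir1,dir2 output directories of two [cmd_fit()] runs on the same
#'   grid.
#' @param out path of the CSV summary to write.
#' @param rois optional ROI label NIfTI restricting the comparison.
#' @return (invisibly) the summary data frame (per metric: mean difference
#'   and limits of agreement).
#' @export
cmd_repeatability <- function(dir1, dir2, out, rois = NULL) {
  rows <- lapply(qti_metric_names(), function(m) {
    f1 <- file.path(dir1, sprintf("%s.nii.gz", m))
    f2 <- file.path(dir2, sprintf("%s.nii.gz", m))
    if (!file.exists(f1) || !file.exists(f2))
      stop_validation("missing metric map ", m, " in one of the runs")
    a <- array(RNifti::readNifti(f1), dim(RNifti::readNifti(f1)))
    b <- array(RNifti::readNifti(f2), dim(RNifti::readNifti(f2)))
    if (!identical(dim(a), dim(b)))
      stop_validation("grid mismatch for metric ", m)
    sel <- if (!is.null(rois)) {
      r <- RNifti::readNifti(rois)
      array(r != 0, dim(a))
    } else array(TRUE, dim(a))
    ba <- bland_altman(a[sel], b[sel])
    data.frame(metric = m, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               lower = ba$lower, upper = ba$upper, n = ba$n)
  })
  summary <- do.call(rbind, rows)
  write.table(summary, out, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(summary)
}

## ---- command-line dispatcher -------------------------------------------

# Minimal --key value parser; flags without a value become TRUE.
parse_cli_args <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

num_list <- function(x) if (is.null(x)) NULL else
  as.numeric(strsplit(x, ",")[[1]])

#' Command-line entry point
#'
#' Dispatches the subcommands `protocol`, `simulate`, `fit`,
#' `waveform-info`, and `repeatability` (see the `cmd_*` functions for the
#' options). Returns the process exit status: 0 on success, 2 for
#' validation errors, 1 for runtime errors.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status.
#' @export
cardioqti_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) stop_validation(
      "usage: cardioqti <protocol|simulate|fit|waveform-info|repeatability> ...")
    cmd <- args[1]
    o <- parse_cli_args(args[-1])
    switch(cmd,
      "protocol" = cmd_protocol(
        out = o$out %||% stop_validation("protocol needs --out"),
        shells = num_list(o$shells) %||% c(0.1, 0.4, 0.7, 1.1, 1.5),
        rotations = num_list(o$rotations) %||% c(10, 20, 30, 40, 50),
        shapes = if (is.null(o$shapes)) c("LTE", "PTE")
                 else strsplit(o$shapes, ",")[[1]],
        seed = as.integer(o$seed %||% 1)),
      "simulate" = cmd_simulate(
        out_dir = o$out %||% stop_validation("simulate needs --out"),
        phantom = o$phantom %||% "two-block",
        angle_deg = as.numeric(o$angle %||% 45),
        shells = num_list(o$shells) %||% c(0.1, 0.4, 0.7, 1.1, 1.5) * 0.3,
        rotations = num_list(o$rotations) %||% c(10, 20, 30, 40, 50),
        seed = as.integer(o$seed %||% 1),
        snr = if (is.null(o$snr)) NULL else as.numeric(o$snr),
        force = isTRUE(o$force)),
      "fit" = cmd_fit(
        volumes = o$volumes %||% stop_validation("fit needs --volumes"),
        scheme = o$scheme %||% stop_validation("fit needs --scheme"),
        out_dir = o$out %||% stop_validation("fit needs --out"),
        mask = o$mask, rois = o$rois, force = isTRUE(o$force)),
      "waveform-info" = cmd_waveform_info(
        paths = o$positional,
        dt = if (is.null(o$dt)) NULL else as.numeric(o$dt),
        gmax = if (is.null(o$gmax)) NULL else as.numeric(o$gmax),
        out = o$out),
      "repeatability" = cmd_repeatability(
        dir1 = o$positional[1], dir2 = o$positional[2],
        out = o$out %||% stop_validation("repeatability needs --out"),
        rois = o$rois),
      stop_validation("unknown command: ", cmd))
    0L
  }
  tryCatch(run(),
           cardioqti_validation_error = function(e) {
             message("error: ", conditionMessage(e)); 2L
           },
           error = function(e) {
             message("error: ", conditionMessage(e)); 1L
           })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
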