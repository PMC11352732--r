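#' Write a multi-echo series as per-echo NIfTI files with a JSON sidecar
#'
#' One 4D (x, y, slice, time) NIfTI per echo plus a sidecar listing
#' `EchoTime` values (ms) and `RepetitionTime` (s) under BIDS-compatible key
#' names. Data are written as doubles so a write/read round trip is bit-exact.
#'
#' @param series a [multiecho_series()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param voxel_mm voxel size stored in the NIfTI header.
#' @return Invisibly, a list with `paths` and `sidecar`.
#' @export
write_multiecho_nifti <- function(series, dir, prefix = "echo",
                                  voxel_mm = c(3.5, 3.5, 3.5)) {
  check_that(inherits(series, "multiecho_series"),
             "series must be a multiecho_series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$data)
  paths <- character(d[4])
  tr <- if (is.finite(series$tr_s)) series$tr_s else 1
  hdr <- RNifti::niftiHeader(list(
    dim = c(4L, d[1], d[2], d[3], d[5], 1L, 1L, 1L),
    pixdim = c(1, voxel_mm, tr, 1, 1, 1),
    datatype = 64L))
  for (e in seq_len(d[4])) {
    img <- RNifti::asNifti(array(series$data[, , , e, ], d[c(1, 2, 3, 5)]),
                           reference = hdr, datatype = "double")
    paths[e] <- file.path(dir, sprintf("%s-%d.nii.gz", prefix, e))
    RNifti::writeNifti(img, paths[e])
  }
  sidecar <- file.path(dir, sprintf("%s.json", prefix))
  jsonlite::write_json(list(EchoTime = series$te_ms,
                            RepetitionTime = series$tr_s,
                            Files = basename(paths)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, sidecar = sidecar))
}

#' Read a multi-echo series from per-echo NIfTI files plus a sidecar
#'
#' Accepts one 4D file per echo (or a single 5D file with the echo axis
#' fourth). Echoes are sorted by ascending `EchoTime` (with a warning if the
#' sidecar listed them out of order); negative intensities are rejected since
#' the pipeline operates on magnitude data.
#'
#' @param paths NIfTI file paths, one per echo (or one 5D file).
#' @param sidecar JSON sidecar path with `EchoTime` (ms) and
#'   `RepetitionTime` (s).
#' @return A [multiecho_series()].
#' @export
read_multiecho_nifti <- function(paths, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  check_that(!is.null(meta$EchoTime),
             "sidecar ", sidecar, " is missing the EchoTime key")
  te <- as.numeric(meta$EchoTime)
  tr <- if (!is.null(meta$RepetitionTime)) as.numeric(meta$RepetitionTime)
        else NA_real_
  if (length(paths) == 1L) {
    arr <- as.array(RNifti::readNifti(paths))
    check_that(length(dim(arr)) == 5L,
               "single-file input must be 5D (x, y, slice, echo, time): ",
               paths)
    check_that(dim(arr)[4] == length(te),
               "echo count of ", paths, " does not match the sidecar")
    data <- arr
  } else {
    check_that(length(paths) == length(te),
               "number of files does not match the sidecar EchoTime list")
    vols <- lapply(paths, function(p) {
      a <- as.array(RNifti::readNifti(p))
      if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
      check_that(length(dim(a)) == 4L, "expected a 4D NIfTI: ", p)
      a
    })
    d1 <- dim(vols[[1]])
    for (i in seq_along(vols)) {
      check_that(all(dim(vols[[i]]) == d1),
                 "inconsistent grid in ", paths[i])
      check_that(all(vols[[i]] >= 0),
                 "negative intensities in ", paths[i],
                 "; magnitude data required")
    }
    data <- array(0, c(d1[1:3], length(te), d1[4]))
    for (e in seq_along(vols)) data[, , , e, ] <- vols[[e]]
  }
  if (is.unsorted(te, strictly = TRUE)) {
    warning("echoes supplied out of TE order; sorting by ascending TE")
    o <- order(te)
    te <- te[o]
    data <- data[, , , o, , drop = FALSE]
  }
  check_that(all(data >= 0), "negative intensities; magnitude data required")
  multiecho_series(data, te, tr)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration with the acquisition defaults (echo times,
#' TR, grid, T2* bounds, noise range, training block, named seeds, paths).
#' Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("te_ms", "tr_s", "grid", "t2_bounds", "noise_range",
               "training", "seeds", "paths")
  extra <- setdiff(names(cfg), allowed)
  check_that(length(extra) == 0,
             "unknown config keys: ", paste(extra, collapse = ", "))
  defaults <- list(te_ms = c(14, 28, 42), tr_s = 2.0, grid = c(64, 64, 1),
                   t2_bounds = c(1, 500), noise_range = c(0, 0.05),
                   training = list(), seeds = list(global = 1L),
                   paths = list())
  cfg <- modifyList(defaults, cfg)
  check_that(all(diff(cfg$te_ms) > 0), "te_ms must be strictly increasing")
  check_that(cfg$tr_s > 0, "tr_s must be positive")
  check_that(cfg$t2_bounds[1] > 0 && cfg$t2_bounds[1] < cfg$t2_bounds[2],
             "invalid t2_bounds")
  check_that(cfg$noise_range[1] >= 0 && cfg$noise_range[2] >= cfg$noise_range[1],
             "invalid noise_range")
  structure(cfg, class = "run_config")
}

#' Run an external multi-echo denoising command on a series
#'
#' Stages the series as per-echo NIfTI files, substitutes `{indir}`,
#' `{sidecar}` and `{outfile}` into `command_template`, runs it, and ingests
#' the resulting 4D NIfTI as a [derived_series()] of kind `MEICA` (or
#' `SDDL_MEICA`). If the command's executable is unavailable the hook reports
#' itself disabled instead of failing, so pipelines can proceed with the
#' internally computed series.
#'
#' @param series a [multiecho_series()].
#' @param command_template shell command with `{indir}`, `{sidecar}`,
#'   `{outfile}` placeholders.
#' @param kind `"MEICA"` or `"SDDL_MEICA"`.
#' @return A [derived_series()], or a list with `status = "disabled"` when the
#'   executable is not on the PATH.
#' @export
meica_hook <- function(series, command_template, kind = "MEICA") {
  check_that(inherits(series, "multiecho_series"),
             "series must be a multiecho_series")
  exe <- strsplit(trimws(command_template), "\\s+")[[1]][1]
  if (!file.exists(exe) && Sys.which(exe) == "") {
    message("meica hook disabled: executable not found: ", exe)
    return(list(status = "disabled", command = command_template))
  }
  indir <- tempfile("meica-in-")
  staged <- write_multiecho_nifti(series, indir, prefix = "echo")
  outfile <- tempfile("meica-out-", fileext = ".nii.gz")
  cmd <- command_template
  cmd <- gsub("{indir}", indir, cmd, fixed = TRUE)
  cmd <- gsub("{sidecar}", staged$sidecar, cmd, fixed = TRUE)
  cmd <- gsub("{outfile}", outfile, cmd, fixed = TRUE)
  status <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("external command failed (exit ", code, "): ", cmd, "\n",
         paste(status, collapse = "\n"))
  }
  check_that(file.exists(outfile), "external command produced no output: ", cmd)
  arr <- as.array(RNifti::readNifti(outfile))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  derived_series(kind, arr,
                 provenance = list(command = cmd, external = TRUE),
                 tr_s = series$tr_s)
}
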