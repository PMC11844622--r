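# Readers, writers, configuration and run manifests.

#' Load 2D slices from a NIfTI volume
#'
#' Slices the volume along the requested axis, min-max normalizes each slice
#' to [0, 1] and drops near-empty slices (foreground fraction below
#' \code{minForeground}); the number of dropped slices is reported with a
#' message.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param axis slicing axis (default 3, axial for standard orientation).
#' @param normalize per-slice min-max normalization (default TRUE); set
#'   "percentile" to clip at the 0.5/99.5 percentiles first (robust variant
#'   for in-vivo data).
#' @param minForeground minimum fraction of pixels above 5 percent of the
#'   slice maximum (default 0.02).
#' @return list of \linkS4class{ImageSlice}.
#' @export
loadNiftiSlices <- function(path, axis = 3L, normalize = TRUE,
                            minForeground = 0.02) {
  if (!file.exists(path))
    stop(sprintf("cannot read NIfTI file '%s': no such file", path),
         call. = FALSE)
  vol <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(vol)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L)
    stop("expected a 2D or 3D volume", call. = FALSE)
  pixdim <- tryCatch(RNifti::pixdim(vol), error = function(e) c(1, 1, 1))
  inPlane <- mean(pixdim[setdiff(1:3, axis)])
  n <- dim(arr)[axis]
  slices <- list()
  dropped <- 0L
  for (i in seq_len(n)) {
    sl <- switch(axis, arr[i, , ], arr[, i, ], arr[, , i])
    rng <- range(sl)
    if (!is.na(normalize) && !identical(normalize, FALSE)) {
      if (identical(normalize, "percentile")) {
        q <- stats::quantile(sl, c(0.005, 0.995))
        sl <- pmin(pmax(sl, q[1]), q[2])
        rng <- range(sl)
      }
      sl <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
    }
    fg <- mean(sl > 0.05 * max(sl, 1e-12))
    if (fg < minForeground) { dropped <- dropped + 1L; next }
    slices[[length(slices) + 1L]] <-
      imageSlice(sl, pixelSpacing = if (is.finite(inPlane) && inPlane > 0)
        inPlane else 1)
  }
  if (dropped > 0L)
    message(sprintf("dropped %d near-empty slice(s)", dropped))
  slices
}

#' Write a stack of slices as a NIfTI volume
#'
#' @param slices list of \linkS4class{ImageSlice} with identical dimensions.
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeNiftiVolume <- function(slices, path) {
  stopifnot(length(slices) >= 1)
  d <- dim(slices[[1]]@pixels)
  arr <- array(0, c(d, length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]@pixels
  sp <- slices[[1]]@pixelSpacing
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(sp, sp, 1)), path,
                     datatype = "float")
  invisible(path)
}

#' Read / write a paired motion archive
#'
#' Archives are serialized \linkS4class{PairedMotionData} objects; the
#' stored config snapshot suffices to regenerate the archive bit-exactly
#' with \code{\link{generateDataset}}.
#'
#' @param archive a \linkS4class{PairedMotionData}.
#' @param path file path.
#' @return \code{readPairedArchive} returns the archive.
#' @export
writePairedArchive <- function(archive, path) {
  stopifnot(is(archive, "PairedMotionData"))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname writePairedArchive
#' @export
readPairedArchive <- function(path) {
  if (!file.exists(path))
    stop(sprintf("archive '%s' does not exist", path), call. = FALSE)
  obj <- readRDS(path)
  if (!is(obj, "PairedMotionData"))
    stop(sprintf("'%s' is not a paired motion archive", path), call. = FALSE)
  validObject(obj)
  obj
}

## Known configuration keys per block (fail-fast on typos).
.configSchema <- list(
  phantom = c("size", "nEllipses", "rimIntensity", "rimThickness", "seed"),
  simulate = c("severity", "nSlabs", "slabWidthRange", "rotBoundDeg",
               "transBoundMm", "centerExclusionFrac"),
  detection = c("depth", "width", "threshold", "peripheralFrac",
                "inputRepr"),
  correction = c("lambdaR", "lambdaL", "lambdaD", "depth", "width",
                 "windowSize", "nHeads", "nSwin", "dcMask"),
  training = c("preset", "batchSize", "lr", "epochs", "steps", "seed",
               "deterministic"))

#' Read and validate a YAML configuration file
#'
#' Unknown blocks or keys are rejected (fail-fast), so typos cannot be
#' silently ignored.
#'
#' @param path YAML file with blocks phantom/simulate/detection/correction/
#'   training (all optional).
#' @return named list of validated blocks.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  for (block in names(cfg)) {
    if (!block %in% names(.configSchema))
      stop(sprintf("unknown config block '%s' (known: %s)", block,
                   paste(names(.configSchema), collapse = ", ")),
           call. = FALSE)
    bad <- setdiff(names(cfg[[block]]), .configSchema[[block]])
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in block '%s': %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg
}

#' Write a run manifest
#'
#' Records the seed, the configuration (plus its MD5 hash) and package/R
#' versions next to a run's outputs, sufficient to reproduce the run in
#' deterministic mode.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed of the run.
#' @return the manifest list, invisibly.
#' @export
writeRunManifest <- function(path, config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  manifest <- list(
    seed = seed,
    config = config,
    configHash = unname(tools::md5sum(tmp)),
    rVersion = as.character(getRversion()),
    package = as.character(utils::packageVersion("kmoco")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
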