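#' Construct a cine series
#'
#' A cine series is one subject's 4D image: an ordered list of 3D intensity
#' volumes covering one cardiac cycle, together with the voxel spacing and
#' the indices of the end-diastolic (ED) and end-systolic (ES) frames.
#'
#' @param frames List of 3D numeric arrays, all with identical dimensions.
#' @param spacing_mm Numeric length-3 vector of positive voxel edge lengths
#'   in millimetres.
#' @param ed_index,es_index 0-based frame indices of end-diastole and
#'   end-systole; must differ.
#' @param subject_id Character identifier.
#' @param metadata Optional named list of free-text tags (e.g. anatomical
#'   complexity category).
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, spacing_mm, ed_index, es_index,
                        subject_id = "subject", metadata = list()) {
  stopifnot(is.list(frames), length(frames) >= 2)
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("every frame must be a 3D array", call. = FALSE)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("all frames must share an identical shape", call. = FALSE)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values", call. = FALSE)
  F <- length(frames)
  ed_index <- as.integer(ed_index); es_index <- as.integer(es_index)
  if (ed_index < 0 || ed_index >= F || es_index < 0 || es_index >= F)
    stop("ed_index/es_index out of range [0, F)", call. = FALSE)
  if (ed_index == es_index)
    stop("ed_index and es_index must differ", call. = FALSE)
  structure(list(subject_id = subject_id, frames = frames,
                 spacing_mm = as.numeric(spacing_mm),
                 ed_index = ed_index, es_index = es_index,
                 metadata = metadata),
            class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<cine_series> %s: %d frames of %dx%dx%d voxels @ %.2fx%.2fx%.2f mm, ED=%d ES=%d\n",
    x$subject_id, length(x$frames), d[1], d[2], d[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    x$ed_index, x$es_index))
  invisible(x)
}

#' Number of frames in a cine series
#' @param series A `cine_series`.
#' @return Integer frame count F.
#' @export
n_frames <- function(series) length(series$frames)

#' Bounding box in voxel indices
#'
#' Boxes are 0-based and half-open: `lower` is the first voxel included,
#' `upper` the first excluded, per axis.
#'
#' @param lower,upper Integer length-3 vectors with `upper > lower`.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(upper <= lower))
    stop("bounding box must have positive extent on every axis", call. = FALSE)
  if (any(lower < 0))
    stop("bounding box lower corner must be non-negative", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "bounding_box")
}

#' Crop a cine series (and its label maps) to a heart bounding box
#'
#' All frames are cropped with the same box so that every frame keeps the
#' same size; the voxel spacing and label values are unchanged.
#'
#' @param series A `cine_series`.
#' @param labels Optional list of 3D integer label arrays (one per frame or
#'   a partial named/indexed list); cropped with the same box.
#' @param box A `bounding_box` lying within the frame shape.
#' @return If `labels` is `NULL`, the cropped `cine_series`; otherwise a
#'   list with elements `series` and `labels`.
#' @export
crop_series <- function(series, box, labels = NULL) {
  stopifnot(inherits(series, "cine_series"), inherits(box, "bounding_box"))
  d <- dim(series$frames[[1]])
  if (any(box$upper > d))
    stop("bounding box exceeds volume bounds", call. = FALSE)
  ix <- (box$lower[1] + 1):box$upper[1]
  iy <- (box$lower[2] + 1):box$upper[2]
  iz <- (box$lower[3] + 1):box$upper[3]
  out <- series
  out$frames <- lapply(series$frames, function(f) f[ix, iy, iz, drop = FALSE])
  if (is.null(labels)) return(out)
  labs <- lapply(labels, function(l) {
    if (is.null(l)) NULL else l[ix, iy, iz, drop = FALSE]
  })
  list(series = out, labels = labs)
}

#' Anchor-based intensity normalization
#'
#' Contrast-enhanced cine MR shows a bright blood pool over dark lung; the
#' intensity scale however varies between acquisitions.  Each frame is
#' rescaled by a two-anchor linear map: the lung anchor (low percentile of
#' the in-box intensities) maps to 0 and the blood anchor (high percentile)
#' maps to 1, with no clipping.
#'
#' @param series A `cine_series` (already cropped to the heart box, so the
#'   percentiles are computed inside the box).
#' @param lung_prob,blood_prob Percentile probabilities of the lung and
#'   blood anchors (defaults 0.05 and 0.95).
#' @return The normalized `cine_series`.
#' @export
normalize_intensity <- function(series, lung_prob = 0.05, blood_prob = 0.95) {
  stopifnot(inherits(series, "cine_series"))
  out <- series
  out$frames <- lapply(series$frames, function(f) {
    q <- quantile(f, c(lung_prob, blood_prob), names = FALSE)
    if (q[2] <= q[1])
      stop("degenerate frame: blood and lung anchors coincide", call. = FALSE)
    (f - q[1]) / (q[2] - q[1])
  })
  out
}

frame_file <- function(dir, t) file.path(dir, sprintf("frame_%02d.nii.gz", t))
label_file <- function(dir, t) file.path(dir, sprintf("label_%02d.nii.gz", t))

#' Read a cine series from NIfTI
#'
#' Accepts either a directory of per-frame 3D NIfTI files named
#' `frame_NN.nii(.gz)` (plus optional `label_NN.nii(.gz)` maps) or a single
#' 4D NIfTI file with time as the 4th axis.  The ED/ES frame indices are
#' never guessed: they must come from the YAML sidecar (default
#' `sidecar.yaml` in the directory) or the `sidecar` argument.
#'
#' @param path Directory or 4D NIfTI file path.
#' @param sidecar Path to a YAML sidecar or a list with at least `ed_index`
#'   and `es_index` (0-based); may carry `subject_id` and `metadata`.
#' @return A list with `series` (a `cine_series`) and `labels` (list of
#'   per-frame label arrays or `NULL` where absent).
#' @export
read_cine <- function(path, sidecar = NULL) {
  if (is.character(sidecar)) sidecar <- yaml::read_yaml(sidecar)
  if (is.null(sidecar) && dir.exists(path)) {
    sc_path <- file.path(path, "sidecar.yaml")
    if (file.exists(sc_path)) sidecar <- yaml::read_yaml(sc_path)
  }
  if (is.null(sidecar$ed_index) || is.null(sidecar$es_index))
    stop("sidecar must supply ed_index and es_index; refusing to guess",
         call. = FALSE)

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) < 2)
      stop("no frame_NN NIfTI files found in ", path, call. = FALSE)
    imgs <- lapply(files, RNifti::readNifti)
    frames <- lapply(imgs, function(im) array(as.numeric(im), dim = dim(im)))
    dims <- lapply(frames, dim)
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      stop("frames have inconsistent shapes", call. = FALSE)
    spacing <- RNifti::pixdim(imgs[[1]])[1:3]
    lab_files <- file.path(path, sprintf("label_%02d.nii.gz",
                                         seq_along(files) - 1L))
    labels <- lapply(lab_files, function(lf) {
      if (!file.exists(lf)) return(NULL)
      im <- RNifti::readNifti(lf)
      array(as.integer(im), dim = dim(im))
    })
  } else {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4)
      stop("expected a 4D NIfTI file or a directory of 3D frames",
           call. = FALSE)
    frames <- lapply(seq_len(d[4]), function(t) {
      array(as.numeric(img[, , , t]), dim = d[1:3])
    })
    spacing <- RNifti::pixdim(img)[1:3]
    labels <- vector("list", d[4])
  }
  series <- cine_series(frames, spacing,
                        ed_index = sidecar$ed_index,
                        es_index = sidecar$es_index,
                        subject_id = sidecar$subject_id %||% "subject",
                        metadata = sidecar$metadata %||% list())
  list(series = series, labels = labels)
}

#' Write a cine series (and label maps) as NIfTI + YAML sidecar
#'
#' Writes one 3D `frame_NN.nii.gz` per frame (float), optional integer
#' `label_NN.nii.gz` maps, and a `sidecar.yaml` holding subject id, ED/ES
#' indices and metadata — the same layout [read_cine()] consumes.
#'
#' @param series A `cine_series`.
#' @param dir Output directory (created if missing).
#' @param labels Optional list of per-frame label arrays (entries may be
#'   `NULL`).
#' @return `dir`, invisibly.
#' @export
write_cine <- function(series, dir, labels = NULL) {
  stopifnot(inherits(series, "cine_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- series$spacing_mm
  for (t in seq_along(series$frames)) {
    im <- RNifti::asNifti(series$frames[[t]], pixdim = sp)
    RNifti::writeNifti(im, frame_file(dir, t - 1L), datatype = "double")
    if (!is.null(labels) && !is.null(labels[[t]])) {
      lm <- RNifti::asNifti(array(as.integer(labels[[t]]),
                                  dim = dim(labels[[t]])), pixdim = sp)
      RNifti::writeNifti(lm, label_file(dir, t - 1L), datatype = "int16")
    }
  }
  yaml::write_yaml(list(subject_id = series$subject_id,
                        ed_index = series$ed_index,
                        es_index = series$es_index,
                        n_frames = length(series$frames),
                        spacing_mm = as.numeric(sp),
                        metadata = series$metadata),
                   file.path(dir, "sidecar.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
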