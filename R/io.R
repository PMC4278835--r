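#' Read a 4D acquisition from disk
#'
#' Accepts either a single 4D NIfTI file (phases in stored 4th-dimension
#' order) or an ordered series of 3D files (NIfTI or MetaImage). A
#' character vector of several paths is treated as a series and read in
#' lexicographic filename order, so zero-padded names (`p01.nii` ...
#' `p20.nii`) load in numeric order; pass the vector pre-ordered to
#' override. A single path containing a glob pattern is expanded first.
#' NIfTI slope/intercept scaling is applied at read time, so values reach
#' the detector as Hounsfield units.
#'
#' @param paths Character vector of file paths, or one path / glob.
#' @param times Optional per-phase acquisition times in seconds.
#' @return A [ct_series()].
#' @export
read_ct_series <- function(paths, times = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1L)
  if (length(paths) == 1L && grepl("[*?]", paths)) {
    paths <- Sys.glob(paths)
    if (length(paths) == 0L) stop("glob matched no files", call. = FALSE)
  }
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("cannot read file '%s'", p), call. = FALSE)
  }
  if (length(paths) == 1L) {
    if (is_nifti_path(paths)) {
      img <- RNifti::readNifti(paths)
      arr <- as.array(img)
      if (length(dim(arr)) != 4L) {
        stop("a single file must be 4D; a lone 3D volume is not a series",
             call. = FALSE)
      }
      sp <- RNifti::pixdim(img)[1:3]
      vols <- lapply(seq_len(dim(arr)[4]), function(k) {
        ct_volume(arr[, , , k, drop = TRUE], spacing = sp)
      })
      return(ct_series(vols, times = times))
    }
    stop("a single MetaImage file is 3D; supply the full series", call. = FALSE)
  }
  paths <- sort(paths)
  vols <- lapply(paths, read_ct_volume)
  ct_series(vols, times = times)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_metaimage_path <- function(path) grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)

#' Read a single 3D volume (NIfTI or MetaImage)
#'
#' @param path Path to a `.nii`/`.nii.gz`, `.mha` or `.mhd` file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path), call. = FALSE)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) {
      stop(sprintf("'%s' is not a 3D volume", path), call. = FALSE)
    }
    return(ct_volume(arr, spacing = RNifti::pixdim(img)[1:3]))
  }
  if (is_metaimage_path(path)) return(read_metaimage(path))
  stop(sprintf("unrecognised volume format: '%s'", path), call. = FALSE)
}

#' Write a series as a single 4D NIfTI file
#'
#' @param series A [ct_series()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_ct_series <- function(series, path) {
  stopifnot(inherits(series, "ct_series"))
  d <- dim(series$phases[[1]]$values)
  arr <- array(0, dim = c(d, length(series$phases)))
  for (k in seq_along(series$phases)) arr[, , , k] <- series$phases[[k]]$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$phases[[1]]$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom to disk (4D NIfTI plus ground-truth sidecar)
#'
#' The sidecar JSON records the generating parameters, the acquisition
#' times and the ground-truth peak phases, so a written phantom remains
#' usable as a labelled test case.
#'
#' @param phantom An `lv_phantom` from [generate_phantom()].
#' @param path Output NIfTI path.
#' @param truth_path Sidecar path; default `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path,
                          truth_path = paste0(path, ".truth.json")) {
  stopifnot(inherits(phantom, "lv_phantom"))
  write_ct_series(phantom$series, path)
  p <- phantom$params
  sidecar <- list(
    synthetic = TRUE,
    lv_peak_phase = phantom$truth$lv_peak_phase,
    rv_peak_phase = phantom$truth$rv_peak_phase,
    times = phantom$series$times,
    chamber_hu = as.list(phantom$truth$chamber_hu),
    params = list(
      extents = p$extents, spacing = p$spacing, n_phases = p$n_phases,
      rr_interval = p$rr_interval, late_phase_offsets = p$late_phase_offsets,
      lv_centre = p$lv_centre, lv_semiaxes = p$lv_semiaxes,
      rv_centre = p$rv_centre, rv_semiaxes = p$rv_semiaxes,
      myocardium_hu = p$myocardium_hu, blood_baseline_hu = p$blood_baseline_hu,
      lung_hu = p$lung_hu, background_hu = p$background_hu,
      lv_curve = unclass(p$lv_curve), rv_curve = unclass(p$rv_curve),
      noise_sigma = p$noise_sigma, seed = p$seed,
      pre_rv_arrival = p$pre_rv_arrival
    )
  )
  jsonlite::write_json(sidecar, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a detection result to JSON
#'
#' The report carries the detected phase (`null` for no-detection), the
#' complete histogram with one entry per phase including zero bins, the
#' voting-voxel count, the effective shrink factor, the parameters used
#' and the tool version, with a stable key order. No-detection is encoded
#' in the JSON, never in an exit status.
#'
#' @param result An `lv_detection` from [detect_lv_phase()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "lv_detection"))
  hist <- as.list(stats::setNames(result$histogram$votes,
                                  as.character(result$histogram$phase)))
  report <- list(
    tool = "lvphase",
    version = as.character(utils::packageVersion("lvphase")),
    detected_phase = if (is.na(result$detected_phase)) NULL
                     else result$detected_phase,
    n_phases = result$n_phases,
    shrink_factor = result$shrink_factor,
    eligible_voxels = result$eligible_voxels,
    params = list(
      hu_lower = result$params$hu_lower,
      hu_upper = result$params$hu_upper,
      increase_mode = result$params$increase_mode,
      increase_value = result$params$increase_value,
      matrix_size = result$params$matrix_size
    ),
    histogram = hist
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a detection result back from JSON
#'
#' @param path Path written by [write_result()].
#' @return An `lv_detection` object equal to the one serialized.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path), call. = FALSE)
  rep <- jsonlite::read_json(path)
  counts <- as.integer(unlist(rep$histogram[as.character(seq_along(rep$histogram))]))
  structure(
    list(
      detected_phase = if (is.null(rep$detected_phase)) NA_integer_
                       else as.integer(rep$detected_phase),
      histogram = new_phase_histogram(counts),
      eligible_voxels = as.integer(rep$eligible_voxels),
      shrink_factor = as.integer(rep$shrink_factor),
      n_phases = as.integer(rep$n_phases),
      params = detection_params(
        hu_lower = rep$params$hu_lower,
        hu_upper = rep$params$hu_upper,
        increase_mode = rep$params$increase_mode,
        increase_value = rep$params$increase_value,
        matrix_size = rep$params$matrix_size
      )
    ),
    class = "lv_detection"
  )
}

metaimage_types <- list(
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4L, signed = FALSE),
  MET_FLOAT = list(what = "double", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE)
)

#' Read a 3D MetaImage volume (.mha or .mhd + raw)
#'
#' Minimal reader for uncompressed scalar MetaImage: plain-text header
#' (either embedded before a `LOCAL` data block in `.mha`, or a separate
#' `.mhd` pointing at a raw file) followed by the voxel data. Standard
#' integer and floating element types and both byte orders are handled;
#' compressed data is not.
#'
#' @param path Path to a `.mha` or `.mhd` file.
#' @return A [ct_volume()].
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read file '%s'", path), call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  header <- character()
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    header <- c(header, line)
    start <- pos + 1L
    if (grepl("^\\s*ElementDataFile\\s*=", line)) {
      data_offset <- start
      break
    }
  }
  fields <- strsplit(header, "\\s*=\\s*")
  keys <- trimws(vapply(fields, `[`, character(1), 1))
  vals <- trimws(vapply(fields, function(f) paste(f[-1], collapse = "="), character(1)))
  h <- stats::setNames(vals, keys)

  if (!is.na(h["CompressedData"]) && toupper(h[["CompressedData"]]) == "TRUE") {
    stop("compressed MetaImage data is not supported", call. = FALSE)
  }
  ndims <- as.integer(h[["NDims"]])
  if (is.na(ndims) || ndims != 3L) stop("only 3D MetaImage is supported", call. = FALSE)
  dims <- as.integer(strsplit(h[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.na(h["ElementSpacing"])) {
    as.numeric(strsplit(h[["ElementSpacing"]], "\\s+")[[1]])
  } else if (!is.na(h["ElementSize"])) {
    as.numeric(strsplit(h[["ElementSize"]], "\\s+")[[1]])
  } else c(1, 1, 1)
  type <- metaimage_types[[h[["ElementType"]]]]
  if (is.null(type)) {
    stop(sprintf("unsupported ElementType '%s'", h[["ElementType"]]), call. = FALSE)
  }
  msb <- FALSE
  for (key in c("ElementByteOrderMSB", "BinaryDataByteOrderMSB")) {
    if (!is.na(h[key])) msb <- toupper(h[[key]]) == "TRUE"
  }
  endian <- if (msb) "big" else "little"
  n <- prod(dims)

  datafile <- h[["ElementDataFile"]]
  if (toupper(datafile) == "LOCAL") {
    con <- rawConnection(raw[data_offset:length(raw)])
    on.exit(close(con))
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) {
      stop(sprintf("cannot read file '%s'", rawpath), call. = FALSE)
    }
    con <- file(rawpath, "rb")
    on.exit(close(con))
    if (!is.na(h["HeaderSize"]) && as.integer(h[["HeaderSize"]]) > 0L) {
      readBin(con, "raw", n = as.integer(h[["HeaderSize"]]))
    }
  }
  vals <- readBin(con, type$what, n = n, size = type$size,
                  signed = type$signed || type$size >= 4L, endian = endian)
  if (length(vals) != n) stop("truncated MetaImage data", call. = FALSE)
  ct_volume(array(as.double(vals), dim = dims), spacing = spacing)
}

#' Write a 3D volume as MetaImage
#'
#' Writes `.mha` (header and raw data in one file) or `.mhd` plus a
#' sibling `.raw`, uncompressed, little-endian.
#'
#' @param volume A [ct_volume()].
#' @param path Output path ending in `.mha` or `.mhd`.
#' @param element_type One of the `MET_*` scalar types; `MET_DOUBLE`
#'   (default) round-trips exactly, integer types truncate.
#' @return `path`, invisibly.
#' @export
write_metaimage <- function(volume, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(volume, "ct_volume"))
  type <- metaimage_types[[element_type]]
  if (is.null(type)) stop(sprintf("unsupported element type '%s'", element_type),
                          call. = FALSE)
  d <- dim(volume$values)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", datafile)
  )
  vals <- as.vector(volume$values)
  if (type$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (local) {
    writeBin(vals, con, size = type$size, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(vals, rawcon, size = type$size, endian = "little")
    close(rawcon)
  }
  invisible(path)
}
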