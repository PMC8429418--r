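# Label-volume and dose-volume I/O. NRRD (NRRD0004, `raw` little-endian or
# `ascii` encodings, `spacings` + `space origin` metadata) is the canonical
# on-disk format; NIfTI is accepted on read when RNifti is available.

.nrrd_types <- c(int = "int", double = "double")

.write_nrrd <- function(data, dims, spacing, origin, path, type,
                        encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by pdtplanr",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("spacings: %.17g %.17g %.17g", spacing[1], spacing[2], spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3]),
    sprintf("encoding: %s", encoding),
    if (encoding == "raw") "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    if (type == "int") {
      writeBin(as.integer(data), con, size = 4, endian = "little")
    } else {
      writeBin(as.double(data), con, size = 8, endian = "little")
    }
  } else {
    writeLines(paste(format(as.vector(data), scientific = TRUE, digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

.parse_nrrd_header <- function(lines) {
  fields <- list()
  for (ln in lines) {
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) fields[[trimws(tolower(m[2]))]] <- trimws(m[3])
  }
  fields
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("truncated NRRD header in ", path, call. = FALSE)
    if (!nzchar(ln)) break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) {
    stop(path, " is not an NRRD file", call. = FALSE)
  }
  f <- .parse_nrrd_header(lines[-1])
  for (need in c("type", "sizes", "encoding")) {
    if (is.null(f[[need]])) {
      stop("NRRD header missing '", need, "' field", call. = FALSE)
    }
  }
  if (is.null(f$spacings) && is.null(f[["space directions"]])) {
    stop("NRRD header lacks voxel spacing metadata ('spacings' or ",
         "'space directions')", call. = FALSE)
  }
  dims <- as.integer(strsplit(f$sizes, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3-D NRRD volumes are supported",
                              call. = FALSE)
  spacing <- if (!is.null(f$spacings)) {
    as.numeric(strsplit(f$spacings, "\\s+")[[1]])
  } else {
    # diagonal of space directions vectors
    vecs <- regmatches(f[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", f[["space directions"]]))[[1]]
    vapply(vecs, function(v) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("NRRD spacing metadata must be positive", call. = FALSE)
  }
  origin <- c(0, 0, 0)
  if (!is.null(f[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", f[["space origin"]]),
                                  ",")[[1]])
  }
  n <- prod(dims)
  type <- f$type
  data <- switch(f$encoding,
    raw = {
      endian <- f$endian %||% "little"
      if (type %in% c("int", "int32", "signed int")) {
        readBin(con, integer(), n = n, size = 4, endian = endian)
      } else if (type %in% c("short", "int16", "signed short")) {
        readBin(con, integer(), n = n, size = 2, endian = endian)
      } else if (type %in% c("uchar", "uint8", "unsigned char")) {
        as.integer(readBin(con, raw(), n = n))
      } else if (type %in% c("double", "float64")) {
        readBin(con, double(), n = n, size = 8, endian = endian)
      } else if (type %in% c("float", "float32")) {
        readBin(con, double(), n = n, size = 4, endian = endian)
      } else {
        stop("unsupported NRRD type '", type, "'", call. = FALSE)
      }
    },
    ascii = scan(con, what = double(), n = n, quiet = TRUE),
    text = scan(con, what = double(), n = n, quiet = TRUE),
    stop("unsupported NRRD encoding '", f$encoding, "'", call. = FALSE)
  )
  if (length(data) != n) stop("NRRD data shorter than header sizes",
                              call. = FALSE)
  list(data = data, dims = dims, spacing = spacing, origin = origin,
       type = type)
}

#' Write a label volume to NRRD
#'
#' @param vol A `label_volume`.
#' @param path Output path (`.nrrd`).
#' @param encoding `"raw"` (little-endian binary) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, encoding = c("raw", "ascii")) {
  stopifnot(inherits(vol, "label_volume"))
  .write_nrrd(vol$labels, dim(vol$labels), vol$spacing, vol$origin, path,
              type = "int", encoding = match.arg(encoding))
}

#' Read a label volume from NRRD or NIfTI
#'
#' Labels must be codes of [label_codes()]; any other value is a validation
#' error naming the first offending voxel. NIfTI files (`.nii`, `.nii.gz`)
#' are read through RNifti when installed.
#'
#' @param path Input file path.
#' @return A `label_volume`.
#' @export
read_label_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    }
    img <- RNifti::readNifti(path)
    data <- as.vector(img)
    dims <- dim(img)
    spacing <- RNifti::pixdim(img)[seq_along(dims)]
    origin <- c(0, 0, 0)
  } else {
    r <- .read_nrrd(path)
    data <- r$data
    dims <- r$dims
    spacing <- r$spacing
    origin <- r$origin
  }
  codes <- label_codes()
  bad <- which(!(data %in% codes))
  if (length(bad)) {
    stop(sprintf("unknown label code %s at voxel index %d", data[bad[1]],
                 bad[1]), call. = FALSE)
  }
  labels <- as.integer(data)
  dim(labels) <- dims
  structure(list(labels = labels, spacing = spacing, origin = origin,
                 meta = list(source_file = path)),
            class = "label_volume")
}

#' Export a dose map (or any scalar field on the grid) to NRRD
#'
#' @param dose A `dose_map` (see [superpose_dose()]) or numeric 3D array.
#' @param path Output path.
#' @param spacing,origin Grid metadata, taken from `dose` when it is a
#'   `dose_map`.
#' @param encoding `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
export_dose_volume <- function(dose, path, spacing = NULL, origin = NULL,
                               encoding = c("raw", "ascii")) {
  if (inherits(dose, "dose_map")) {
    arr <- dose$fluence
    spacing <- spacing %||% dose$spacing
    origin <- origin %||% dose$origin
  } else {
    arr <- dose
    spacing <- spacing %||% c(1, 1, 1)
    origin <- origin %||% c(0, 0, 0)
  }
  stopifnot(length(dim(arr)) == 3)
  .write_nrrd(arr, dim(arr), spacing, origin, path, type = "double",
              encoding = match.arg(encoding))
}

#' Read a dose volume written by [export_dose_volume()]
#' @param path NRRD file path.
#' @return A `dose_map` with `fluence`, `spacing`, `origin`.
#' @export
read_dose_volume <- function(path) {
  r <- .read_nrrd(path)
  arr <- as.double(r$data)
  dim(arr) <- r$dims
  structure(list(fluence = arr, spacing = r$spacing, origin = r$origin,
                 provenance = list(source_file = path)),
            class = "dose_map")
}

#' Binary iso-dose mask at a named threshold
#'
#' @param dose A `dose_map` or numeric array.
#' @param threshold Fluence threshold, J/mm^2.
#' @return Logical 3D array, `TRUE` where dose >= threshold (dose > 0 when
#'   `threshold` is 0).
#' @export
iso_mask <- function(dose, threshold) {
  arr <- if (inherits(dose, "dose_map")) dose$fluence else dose
  if (threshold <= 0) arr > 0 else arr >= threshold
}
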