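#' 3D image volume
#'
#' Container for a 3D scalar grid with physical geometry. Voxel indices are
#' 0-based and the physical position of voxel `(i,j,k)` is
#' `origin + c(i,j,k) * spacing` (axis-aligned geometry only; direction
#' cosines other than identity are rejected at read time).
#'
#' @param data numeric 3D array of intensities (HU-like, arbitrary units).
#' @param spacing positive numeric triple, mm per voxel along each axis.
#' @param origin numeric triple, mm position of voxel (0,0,0).
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(5, 4, 3)), spacing = c(1, 1, 4))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3(data)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be a positive finite triple", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite triple", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary structure mask
#'
#' A delineated organ on the grid of an associated [image_volume()]. Any
#' non-zero input value is mapped to 1 (binarization is idempotent).
#'
#' @param data 3D array; non-zero entries become foreground.
#' @inheritParams image_volume
#' @return Object of class `structure_mask` (also inherits `image_volume`)
#'   whose `data` contains only 0 and 1.
#' @export
structure_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- image_volume(data, spacing, origin)
  storage.mode(v$data) <- "double"
  v$data[] <- as.double(v$data != 0)
  class(v) <- c("structure_mask", "image_volume")
  v
}

#' Dense displacement field
#'
#' Per-voxel 3-vectors in voxel units carrying the geometry of the fixed
#' image. The stored vectors follow the resampling (pull-back) convention:
#' the moving-image position corresponding to fixed voxel `v` is
#' `v + field(v)` (see [warp_image()]); millimetre magnitudes are obtained by
#' multiplying each component by the spacing.
#'
#' @param vectors numeric 4D array of dimension `c(nx, ny, nz, 3)`.
#' @inheritParams image_volume
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with 3 components in the last dimension",
         call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field components must be finite everywhere", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be a positive triple", call. = FALSE)
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "displacement_field")
}

as_array3 <- function(x) {
  x <- as.array(x)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("expected a 3D array", call. = FALSE)
  if (any(dim(x) < 1L)) stop("all grid dimensions must be >= 1", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

vol_dims <- function(x) {
  if (inherits(x, "displacement_field")) dim(x$vectors)[1:3] else dim(x$data)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vol_dims(a), vol_dims(b)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

stopifnot_same_geometry <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(sprintf("%s have mismatched geometry: dims %s vs %s", what,
                 paste(vol_dims(a), collapse = "x"),
                 paste(vol_dims(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- vol_dims(x)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "structure_mask")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$data != 0)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- vol_dims(x)
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d voxels (voxel units), max |u| = %.3f vox\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

format_of <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  stop(sprintf("unsupported volume format: '%s' (use .nii, .nii.gz, .mha or .mhd)",
               basename(path)), call. = FALSE)
}

# ---- NIfTI backend (RNifti) -------------------------------------------------

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))  # strip niftiImage attributes
  nd <- length(dim(arr))
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  # axis-aligned positive-diagonal direction only
  expected <- diag(spacing)
  if (max(abs(rot - expected)) > 1e-3 * max(spacing))
    stop(sprintf("'%s' has a non-axis-aligned direction matrix; only identity orientation is supported",
                 basename(path)), call. = FALSE)
  list(array = arr, ndim = nd, spacing = as.numeric(spacing),
       origin = as.numeric(xf[1:3, 4]))
}

nifti_write <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, max(nd - 3L, 0L)))
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# ---- MetaImage backend (hand-rolled; no installed R reader exists) ----------

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

meta_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) stop(sprintf("malformed MetaImage header line: '%s'", line),
                               call. = FALSE)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$ObjectType, "Image") || !identical(hdr$NDims, "3"))
    stop("only 3D MetaImage Image objects are supported", call. = FALSE)
  if (identical(toupper(hdr$CompressedData %||% "FALSE"), "TRUE"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  dims <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(hdr$ElementSpacing %||% "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$Offset %||% "0 0 0"), "\\s+")[[1]])
  tm <- as.numeric(strsplit(trimws(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1"), "\\s+")[[1]])
  if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
    stop(sprintf("'%s' has a non-identity TransformMatrix; only identity orientation is supported",
                 basename(path)), call. = FALSE)
  k <- as.integer(hdr$ElementNumberOfChannels %||% "1")
  tp <- .met_types[[hdr$ElementType %||% ""]]
  if (is.null(tp)) stop(sprintf("unsupported ElementType '%s'", hdr$ElementType),
                        call. = FALSE)
  endian <- if (identical(toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE"), "TRUE"))
    "big" else "little"
  n <- prod(dims) * k
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_vals <- readBin(con, what = tp$what, n = n, size = tp$size,
                        signed = tp$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage data file '%s' not found", rawpath), call. = FALSE)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw_vals <- readBin(con2, what = tp$what, n = n, size = tp$size,
                        signed = tp$signed, endian = endian)
  }
  if (length(raw_vals) != n)
    stop("MetaImage data shorter than declared DimSize", call. = FALSE)
  arr <- if (k == 1L) array(as.double(raw_vals), dims) else
    aperm(array(as.double(raw_vals), c(k, dims)), c(2, 3, 4, 1))
  list(array = arr, channels = k, spacing = spacing, origin = origin)
}

meta_write <- function(arr, spacing, origin, path, element_type = "MET_DOUBLE") {
  dims <- dim(arr)
  k <- if (length(dims) == 4L) dims[4] else 1L
  tp <- .met_types[[element_type]]
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    if (k > 1L) sprintf("ElementNumberOfChannels = %d", k),
    sprintf("ElementType = %s", element_type)
  )
  vals <- if (k == 1L) as.vector(arr) else as.vector(aperm(arr, c(4, 1, 2, 3)))
  if (tp$what == "integer") vals <- as.integer(round(vals))
  ext <- format_of(path)
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    header_txt <- paste0(paste(c(hdr, "ElementDataFile = LOCAL"), collapse = "\n"), "\n")
    writeChar(header_txt, con, eos = NULL)
    writeBin(vals, con, size = tp$size, endian = "little")
  } else {
    rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    writeLines(c(hdr, sprintf("ElementDataFile = %s", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(vals, con, size = tp$size, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- user-facing I/O --------------------------------------------------------

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Intensities are passed through unmodified. Files with non-identity
#' direction matrices are rejected rather than silently reoriented.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  fmt <- format_of(path)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  r <- if (fmt == "nifti") nifti_read(path) else meta_read(path)
  arr <- r$array
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s' is not a scalar 3D volume (dims: %s); use read_field() for vector data",
                 basename(path), paste(dim(arr), collapse = "x")), call. = FALSE)
  image_volume(arr, r$spacing, r$origin)
}

#' Write a 3D volume
#'
#' Volumes are stored as double precision so a write/read round trip is
#' bit-identical.
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  fmt <- format_of(path)
  if (fmt == "nifti") {
    nifti_write(volume$data, volume$spacing, volume$origin, path, datatype = "double")
  } else {
    meta_write(volume$data, volume$spacing, volume$origin, path,
               element_type = "MET_DOUBLE")
  }
  invisible(path)
}

#' Read a structure mask aligned to a reference volume
#'
#' Any non-zero stored value becomes foreground (1); grid dimensions must
#' match the reference exactly. The reference's spacing and origin are
#' adopted.
#'
#' @param path mask file path.
#' @param reference the [image_volume()] the mask is aligned to.
#' @return A [structure_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  v <- read_volume(path)
  if (!identical(vol_dims(v), vol_dims(reference)))
    stop(sprintf("mask dimensions %s do not match reference dimensions %s",
                 paste(vol_dims(v), collapse = "x"),
                 paste(vol_dims(reference), collapse = "x")), call. = FALSE)
  structure_mask(v$data, reference$spacing, reference$origin)
}

#' Write a structure mask
#'
#' Masks are written as unsigned 8-bit integers; values stay in \{0, 1\}
#' across a round trip.
#'
#' @param mask a [structure_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  fmt <- format_of(path)
  if (fmt == "nifti") {
    nifti_write(mask$data, mask$spacing, mask$origin, path, datatype = "uint8")
  } else {
    meta_write(mask$data, mask$spacing, mask$origin, path, element_type = "MET_UCHAR")
  }
  invisible(path)
}

#' Read / write a displacement field
#'
#' Fields are stored as 3-component vector volumes: a 5D NIfTI
#' (`nx x ny x nz x 1 x 3`) or a MetaImage with `ElementNumberOfChannels = 3`.
#' Components are per-axis displacements in voxel units (the resampling
#' convention of [displacement_field()]); spacing is carried in the header so
#' millimetre magnitudes can be derived.
#'
#' @param path field file path.
#' @return [read_field()] returns a [displacement_field()].
#' @export
read_field <- function(path) {
  fmt <- format_of(path)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  r <- if (fmt == "nifti") nifti_read(path) else meta_read(path)
  arr <- r$array
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, c(d[1:3], d[5]))
    d <- dim(arr)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf("'%s' is not a 3-component vector volume (dims: %s)",
                 basename(path), paste(dim(r$array), collapse = "x")), call. = FALSE)
  displacement_field(arr, r$spacing, r$origin)
}

#' @param field a [displacement_field()].
#' @rdname read_field
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  fmt <- format_of(path)
  if (fmt == "nifti") {
    d <- dim(field$vectors)
    arr5 <- array(field$vectors, c(d[1:3], 1L, 3L))
    nifti_write(arr5, field$spacing, field$origin, path, datatype = "double")
  } else {
    meta_write(field$vectors, field$spacing, field$origin, path,
               element_type = "MET_DOUBLE")
  }
  invisible(path)
}
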