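#' @useDynLib kneemorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical anatomical axis convention shared by every volume and every
# derived 2D product: i = mediolateral (ML), j = anteroposterior (AP),
# k = superoinferior (SI).
.axis_convention <- c(i = "ML", j = "AP", k = "SI")

#' Structure roles recognised in knee label maps
#'
#' The closed set of anatomical structure roles a label map may assign to
#' integer labels: the two bones, the two cartilage plates, the two menisci,
#' and the bone-derived regions of interest (subchondral femoral surface and
#' the two tibial plateaus), plus `background` which must map to 0.
#'
#' @return Character vector of valid role names.
#' @export
knee_roles <- function() {
  c("background", "femur", "tibia", "femoral_cartilage", "tibial_cartilage",
    "medial_meniscus", "lateral_meniscus", "roi_femoral_subchondral",
    "roi_medial_tibial_plateau", "roi_lateral_tibial_plateau")
}

#' Voxel grid geometry
#'
#' Describes the geometry of a 3D voxel grid: array shape, physical spacing
#' per axis in millimetres, and the physical position of the centre of voxel
#' `[1,1,1]`. Axis meaning is fixed by the package-wide canonical convention
#' (i = mediolateral, j = anteroposterior, k = superoinferior) and recorded
#' on the object.
#'
#' @param shape Integer vector of length 3, all `>= 1`.
#' @param spacing_mm Numeric vector of length 3, all `> 0` (mm).
#' @param origin_mm Numeric vector of length 3 (mm); default `c(0,0,0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(shape) == 3L, length(spacing_mm) == 3L, length(origin_mm) == 3L)
  if (any(shape < 1L)) stop("voxel_grid: all shape components must be >= 1")
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("voxel_grid: all spacing components must be finite and > 0")
  structure(list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm,
                 axes = .axis_convention),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %s, spacing %s mm, origin (%s) mm [i=ML, j=AP, k=SI]\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing_mm, 6), collapse = " x "),
              paste(signif(x$origin_mm, 6), collapse = ", ")))
  invisible(x)
}

#' Labeled 3D volume
#'
#' A 3D integer label array with its grid geometry and a label map assigning
#' a structure role to every integer present. Background must be coded 0.
#'
#' @param labels 3D integer array.
#' @param grid A [voxel_grid()] whose shape matches `dim(labels)`.
#' @param label_map Named integer vector: `names` are roles from
#'   [knee_roles()], values are the label codes used in `labels`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, label_map) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(dim(labels)) != 3L) stop("label_volume: labels must be a 3D array")
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label_volume: label array shape does not match grid shape")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      stop("label_volume: non-integral values in label array (label-integrity error)")
    storage.mode(labels) <- "integer"
  }
  label_map <- .validate_label_map(label_map)
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(present, unname(label_map))
  if (length(missing))
    stop("label_volume: labels present but absent from label_map: ",
         paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels, label_map = label_map),
            class = "label_volume")
}

.validate_label_map <- function(label_map) {
  lm <- as.integer(label_map)
  names(lm) <- names(label_map)
  if (is.null(names(lm)) || any(!nzchar(names(lm))))
    stop("label_map must be a named integer vector (role -> code)")
  bad <- setdiff(names(lm), knee_roles())
  if (length(bad))
    stop("label_map contains unknown structure roles: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(lm)) || anyDuplicated(lm))
    stop("label_map roles and codes must both be unique")
  if (!"background" %in% names(lm)) lm <- c(background = 0L, lm)
  if (lm[["background"]] != 0L) stop("label_map: background must map to 0")
  if (any(lm < 0L)) stop("label_map: codes must be non-negative")
  lm
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume\n")
  print(x$grid)
  tab <- table(factor(as.vector(x$labels), levels = unname(x$label_map)))
  for (role in names(x$label_map)) {
    code <- x$label_map[[role]]
    cat(sprintf("  %2d %-26s %d voxels\n", code, role, tab[[as.character(code)]]))
  }
  invisible(x)
}

#' Grayscale 3D volume
#'
#' @param values 3D numeric array of finite values (arbitrary MR units).
#' @param grid A [voxel_grid()] matching `dim(values)`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(dim(values)) != 3L) stop("intensity_volume: values must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("intensity_volume: value array shape does not match grid shape")
  if (any(!is.finite(values))) stop("intensity_volume: non-finite values")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("intensity_volume, range", paste(signif(range(x$values), 6), collapse = " .. "), "\n")
  print(x$grid)
  invisible(x)
}

#' Test whether two voxel grids are the same
#'
#' All multi-structure operations in the package require their inputs to live
#' on one shared grid; no resampling is ever performed (silent resampling
#' corrupts thickness measurements). Grids agree when shapes are equal and
#' spacing and origin agree within `tol_mm`.
#'
#' @param a,b [voxel_grid()] objects (or volumes carrying a `$grid`).
#' @param tol_mm Agreement tolerance in mm, default `1e-6`.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, tol_mm = 1e-6) {
  ga <- if (inherits(a, "voxel_grid")) a else a$grid
  gb <- if (inherits(b, "voxel_grid")) b else b$grid
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing_mm - gb$spacing_mm) <= tol_mm) &&
    all(abs(ga$origin_mm - gb$origin_mm) <= tol_mm)
}

.sidecar_path <- function(path) {
  base <- sub("\\.nii\\.gz$|\\.nii$|\\.nrrd$", "", path)
  paste0(base, ".labels.json")
}

#' Read a 3D volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`, via RNifti) and NRRD
#' (`.nrrd`, attached header, raw or gzip encoding). Voxel spacing and origin
#' are taken from file metadata. NIfTI volumes stored in a non-RAS
#' orientation are reoriented to the canonical i=ML, j=AP, k=SI convention
#' on read (identifying RAS x,y,z with ML,AP,SI). When `expected = "label"`,
#' a JSON sidecar `<file>.labels.json` written by [write_volume()] restores
#' the label map; otherwise a label map must be supplied.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param expected Either `"label"` or `"intensity"`.
#' @param label_map Optional named integer vector overriding the sidecar.
#' @return A [label_volume()] or [intensity_volume()].
#' @export
read_volume <- function(path, expected = c("label", "intensity"), label_map = NULL) {
  expected <- match.arg(expected)
  if (!file.exists(path)) stop("read_volume: file does not exist: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("read_volume: unreadable NIfTI file: ",
                                             conditionMessage(e)))
    if (!identical(RNifti::orientation(img), "RAS"))
      RNifti::orientation(img) <- "RAS"
    arr <- as.array(img)
    if (length(dim(arr)) < 3L)
      stop("read_volume: volume has fewer than 3 dimensions")
    if (length(dim(arr)) > 3L) {
      if (prod(dim(arr)[-(1:3)]) != 1L)
        stop("read_volume: only single-channel 3D volumes are supported")
      dim(arr) <- dim(arr)[1:3]
    }
    spacing <- as.numeric(RNifti::pixdim(img))[1:3]
    xf <- RNifti::xform(img)
    origin <- as.numeric(xf[1:3, 4])
    attributes(arr) <- list(dim = dim(arr))   # drop NIfTI image attributes
    grid <- voxel_grid(dim(arr), spacing, origin)
  } else if (grepl("\\.nrrd$", path)) {
    nr <- .read_nrrd(path)
    arr <- nr$data
    if (length(dim(arr)) < 3L)
      stop("read_volume: volume has fewer than 3 dimensions")
    grid <- voxel_grid(dim(arr), nr$spacing, nr$origin)
  } else {
    stop("read_volume: unrecognized format (expect .nii, .nii.gz or .nrrd): ", path)
  }
  if (expected == "intensity") return(intensity_volume(arr, grid))
  if (any(arr != round(arr)))
    stop("read_volume: non-integral voxel values but expected = \"label\" (label-integrity error)")
  storage.mode(arr) <- "integer"
  if (is.null(label_map)) {
    sc <- .sidecar_path(path)
    if (file.exists(sc)) {
      lst <- jsonlite::read_json(sc, simplifyVector = TRUE)
      label_map <- stats::setNames(as.integer(unlist(lst)), names(lst))
    } else {
      stop("read_volume: expected = \"label\" but no label_map given and no sidecar at ", sc)
    }
  }
  label_volume(arr, grid, label_map)
}

#' Write a 3D volume to disk
#'
#' Writes NIfTI-1 or NRRD depending on the file extension. Round-trips
#' through [read_volume()] with identical values and geometry within
#' 1e-6 mm. Label volumes also write a `<file>.labels.json` sidecar holding
#' the label map.
#'
#' @param vol A [label_volume()] or [intensity_volume()].
#' @param path Destination ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path))
  is_label <- inherits(vol, "label_volume")
  arr <- if (is_label) vol$labels else vol$values
  g <- vol$grid
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- g$spacing_mm
    xf <- diag(c(g$spacing_mm, 1))
    xf[1:3, 4] <- g$origin_mm
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path)) {
    .write_nrrd(arr, g$spacing_mm, g$origin_mm, path, integer_type = is_label)
  } else {
    stop("write_volume: unrecognized extension (expect .nii, .nii.gz or .nrrd): ", path)
  }
  if (is_label)
    jsonlite::write_json(as.list(vol$label_map), .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

# --- minimal NRRD dialect -----------------------------------------------
# No installed R package handles NRRD, so a small reader/writer for the
# dialect this package emits is provided: attached header, little-endian,
# types double / int32, encodings raw and gzip, dimensions 2 or 3,
# axis-aligned "space directions". Sufficient for lossless round-trips of
# label/intensity volumes and 2D mask grids.

.write_nrrd <- function(arr, spacing, origin, path, integer_type) {
  nd <- length(dim(arr))
  type <- if (integer_type) "int" else "double"
  dirs <- vapply(seq_len(nd), function(a) {
    v <- numeric(nd); v[a] <- spacing[a]
    paste0("(", paste(formatC(v, format = "g", digits = 17), collapse = ","), ")")
  }, character(1))
  hdr <- c("NRRD0004",
           "# minimal NRRD written by kneemorph",
           paste0("type: ", type),
           paste0("dimension: ", nd),
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           paste0("space dimension: ", nd),
           paste0("space directions: ", paste(dirs, collapse = " ")),
           paste0("space origin: (",
                  paste(formatC(origin[seq_len(nd)], format = "g", digits = 17),
                        collapse = ","), ")"),
           "endian: little",
           "encoding: gzip",
           "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  payload <- if (integer_type) {
    writeBin(memCompress(writeBin(as.integer(arr), raw(), size = 4L,
                                  endian = "little"), "gzip"), con)
  } else {
    writeBin(memCompress(writeBin(as.double(arr), raw(), size = 8L,
                                  endian = "little"), "gzip"), con)
  }
  invisible(path)
}

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD"))
    stop("read_volume: not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("read_volume: truncated NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  type <- fields[["type"]]
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  nd <- length(sizes)
  enc <- fields[["encoding"]]
  parse_tuple <- function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  spacing <- rep(1, nd)
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    for (a in seq_along(toks)) spacing[a] <- parse_tuple(toks[a])[a]
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
  }
  origin <- rep(0, nd)
  if (!is.null(fields[["space origin"]])) origin <- parse_tuple(fields[["space origin"]])
  payload <- readBin(con, raw(), n = file.size(path))
  if (identical(enc, "gzip")) payload <- memDecompress(payload, "gzip")
  else if (!identical(enc, "raw"))
    stop("read_volume: unsupported NRRD encoding: ", enc)
  n <- prod(sizes)
  data <- switch(type,
    "int" = , "int32" = , "signed int" =
      readBin(payload, integer(), n = n, size = 4L, endian = "little"),
    "short" = , "int16" =
      readBin(payload, integer(), n = n, size = 2L, endian = "little"),
    "uchar" = , "uint8" =
      readBin(payload, integer(), n = n, size = 1L, signed = FALSE),
    "double" = readBin(payload, double(), n = n, size = 8L, endian = "little"),
    "float" = readBin(payload, double(), n = n, size = 4L, endian = "little"),
    stop("read_volume: unsupported NRRD type: ", type))
  if (length(data) < n) stop("read_volume: truncated NRRD payload")
  dim(data) <- sizes
  list(data = data, spacing = spacing, origin = origin)
}

# Binary mask (logical 3D array) for one structure role.
.role_mask <- function(vol, role) {
  stopifnot(inherits(vol, "label_volume"))
  if (!role %in% names(vol$label_map))
    stop("structure role '", role, "' absent from label_map (structure-missing error)")
  vol$labels == vol$label_map[[role]]
}

# Physical coordinates (mm) of voxel centres along each axis.
.axis_coords <- function(grid) {
  lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing_mm[a])
}
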