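# File formats: 16-bit PGM images, ASCII STL meshes, JSON-lines annotations
# and JSON manifests. All numeric serialization uses full precision so poses
# round-trip bit-exactly.

FP_SCHEMA <- "fluoropose-annotations/1"

#' Read and write 16-bit grayscale PGM images
#'
#' Binary (P5) PGM with maxval 65535, big-endian, one row per image row.
#' Intensities in `[0, 1]` are quantized to 16 bits on write and rescaled on
#' read.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `read_pgm` returns the image matrix in `[0, 1]`.
#' @export
write_pgm <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", sprintf("%d %d", ncol(image), nrow(image)), "65535"), con)
  vals <- as.integer(round(pmin(pmax(t(image), 0), 1) * 65535))
  writeBin(vals, con, size = 2, endian = "big")
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P5")) stop("read_pgm: not a binary PGM (P5) file")
  dims <- scan(text = readLines(con, n = 1), quiet = TRUE)
  maxval <- scan(text = readLines(con, n = 1), quiet = TRUE)
  vals <- readBin(con, "integer", n = dims[1] * dims[2], size = 2,
                  signed = FALSE, endian = "big")
  t(matrix(vals / maxval, nrow = dims[1], ncol = dims[2]))
}

#' Read and write ASCII STL meshes
#'
#' @param mesh a list with `vertices` (n x 3, mm) and `faces` (n x 3,
#'   1-based), e.g. an [make_fiducial()] object.
#' @param path file path.
#' @param name solid name written to the file.
#' @return `read_stl` returns a list with `vertices` and `faces`
#'   (vertices de-duplicated exactly).
#' @export
write_stl <- function(mesh, path, name = "fiducial") {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  lines <- c(paste("solid", name),
             as.vector(rbind(paste("facet normal", fmt(nrm)),
                             "outer loop",
                             paste("vertex", fmt(p1)),
                             paste("vertex", fmt(p2)),
                             paste("vertex", fmt(p3)),
                             "endloop", "endfacet")),
             paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex ", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  list(vertices = verts,
       faces = matrix(as.integer(idx), ncol = 3, byrow = TRUE))
}

pose_to_list <- function(p) list(x = p$x, y = p$y, alpha = p$alpha,
                                 tau = p$tau, d = p$d)

pose_from_list <- function(l) {
  need <- c("x", "y", "alpha", "tau", "d")
  miss <- setdiff(need, names(l))
  if (length(miss))
    stop(sprintf("annotation record: missing pose field(s): %s",
                 paste(miss, collapse = ", ")))
  pose(l$x, l$y, alpha = l$alpha, tau = l$tau, d = l$d)
}

#' Read and write JSON-lines pose annotations
#'
#' One header line (schema version, units, coordinate conventions) followed
#' by one JSON object per image record (`index`, `pose`, `seed`, `fiducial`,
#' optional `path`). Numeric fields are serialized at full precision, so a
#' write/read cycle is lossless.
#'
#' @param ds an `fp_dataset` (or a list with a `records` field).
#' @param path file path.
#' @return `read_annotations` returns the list of records (with `pose`
#'   restored as [pose()] objects); malformed records and schema mismatches
#'   are reported with their line number.
#' @export
write_annotations <- function(ds, path) {
  header <- list(schema = FP_SCHEMA,
                 units = list(position = "px", angles = "deg", depth = "mm"),
                 convention = "x right, y down; alpha from +x toward +y; tau in [-90,90]")
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)),
             vapply(ds$records, function(r) {
               as.character(jsonlite::toJSON(
                 list(index = r$index, pose = pose_to_list(r$pose),
                      seed = r$seed, fiducial = r$fiducial,
                      path = if (is.null(r$path)) NULL else basename(r$path)),
                 auto_unbox = TRUE, digits = I(17), null = "null"))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_annotations: empty file")
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$schema, FP_SCHEMA))
    stop(sprintf("read_annotations: schema mismatch at line 1 (found '%s', expected '%s')",
                 header$schema, FP_SCHEMA))
  lapply(seq_along(lines[-1]), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i + 1]),
                    error = function(e)
                      stop(sprintf("read_annotations: malformed record at line %d: %s",
                                   i + 1, conditionMessage(e)), call. = FALSE))
    rec$pose <- tryCatch(pose_from_list(rec$pose), error = function(e)
      stop(sprintf("read_annotations: line %d: %s", i + 1, conditionMessage(e)),
           call. = FALSE))
    rec
  })
}

#' Read and write the dataset manifest
#'
#' A single JSON file holding the full generation configuration (fiducial,
#' geometry, pose ranges, background, split, master seed) plus the image
#' file list; together with the package version this makes every dataset
#' reproducible from its manifest alone.
#'
#' @param ds an `fp_dataset`.
#' @param path file path.
#' @param check_images for `read_manifest`: verify that all referenced image
#'   files exist next to the manifest.
#' @return `read_manifest` returns the manifest as a list.
#' @export
write_manifest <- function(ds, path) {
  m <- list(schema = "fluoropose-manifest/1",
            config = ds$config,
            images = vapply(ds$records, function(r)
              if (is.null(r$path)) "" else basename(r$path), character(1)))
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_images = TRUE) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(m$schema, "fluoropose-manifest/1"))
    stop("read_manifest: unrecognized manifest schema")
  if (check_images && length(m$images) && any(nzchar(m$images))) {
    missing <- m$images[nzchar(m$images) &
                          !file.exists(file.path(dirname(path), m$images))]
    if (length(missing))
      stop(sprintf("read_manifest: %d referenced image(s) missing, e.g. '%s'",
                   length(missing), missing[1]))
  }
  m
}
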