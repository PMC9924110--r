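#' Read and write integrated depth-dose curves as CSV
#'
#' The on-disk dialect is a comma-separated, UTF-8, header-row file with
#' columns `depth_mm,signal`; values round-trip at full double precision.
#'
#' @param path file path.
#' @return `read_idd_csv()` returns a [depth_dose_curve()].
#' @export
read_idd_csv <- function(path) {
  pw_check(file.exists(path), sprintf("file not found: %s", path),
           "protonWET_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  pw_check(all(c("depth_mm", "signal") %in% names(df)),
           "IDD CSV must have columns `depth_mm` and `signal`",
           "protonWET_malformed_header_error")
  pw_check(all(diff(df$depth_mm) > 0),
           "IDD depth column must be strictly increasing",
           "protonWET_monotonicity_error")
  depth_dose_curve(df$depth_mm, df$signal)
}

#' @rdname read_idd_csv
#' @param curve a [depth_dose_curve()] to write.
#' @export
write_idd_csv <- function(curve, path) {
  pw_check(inherits(curve, "depth_dose_curve"), "`curve` must be a depth_dose_curve")
  df <- data.frame(depth_mm = curve$depths_mm, signal = curve$signal)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration curve from CSV node tables
#'
#' Accepts either the two-stage form — an `hu,density` table plus a
#' `density,rsp` table — or a single-stage `hu,rsp` table.  Monotonicity is
#' validated at load time.
#'
#' @param hu_path CSV with columns `hu,density` (two-stage) or `hu,rsp`
#'   (single-stage).
#' @param rsp_path optional CSV with columns `density,rsp`.
#' @return A [calibration_curve()].
#' @export
read_calibration_csv <- function(hu_path, rsp_path = NULL) {
  pw_check(file.exists(hu_path), sprintf("file not found: %s", hu_path),
           "protonWET_io_error")
  a <- utils::read.csv(hu_path, check.names = FALSE)
  pw_check("hu" %in% names(a), "calibration CSV must have an `hu` column",
           "protonWET_malformed_header_error")
  if ("rsp" %in% names(a) && !"density" %in% names(a)) {
    return(calibration_curve(hu = a$hu, rsp = a$rsp))
  }
  pw_check("density" %in% names(a),
           "calibration CSV must have a `density` (or `rsp`) column",
           "protonWET_malformed_header_error")
  if (is.null(rsp_path)) {
    return(calibration_curve(hu = a$hu, density = a$density))
  }
  b <- utils::read.csv(rsp_path, check.names = FALSE)
  pw_check(all(c("density", "rsp") %in% names(b)),
           "density-to-RSP CSV must have columns `density` and `rsp`",
           "protonWET_malformed_header_error")
  calibration_curve(hu = a$hu, density = a$density,
                    density_nodes = b$density, rsp = b$rsp)
}

# ---- minimal NRRD0004 support for regular 3-D grids ------------------------

nrrd_type_info <- list(
  double  = list(what = "double",  size = 8L),
  float   = list(what = "double",  size = 4L),
  uint8   = list(what = "integer", size = 1L)
)

#' Read and write voxel grids as NRRD
#'
#' A minimal NRRD0004 implementation sufficient for the regular 3-D grids
#' this package uses: types `double`, `float` and `uint8`, encodings
#' `gzip`, `raw` and `text`, little-endian, axis sizes in x-fastest order
#' (`sizes: nx ny nz`, matching the column-major array layout), with voxel
#' spacing in `space directions` and the grid corner in `space origin`.
#' The grid kind is stored in a `kind` key-value pair and restored on read.
#' Spacing and origin round-trip at full precision.
#'
#' @param path file path.
#' @return `read_nrrd()` returns a [vox_grid()].
#' @export
read_nrrd <- function(path) {
  pw_check(file.exists(path), sprintf("file not found: %s", path),
           "protonWET_io_error")
  bytes <- readBin(path, "raw", file.size(path))
  nl <- which(bytes == as.raw(10L))
  header_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { header_end <- p; break }
    prev <- p
  }
  pw_check(!is.na(header_end), "no blank line terminating the NRRD header",
           "protonWET_malformed_header_error")
  header <- strsplit(rawToChar(bytes[seq_len(header_end - 1L)]), "\n",
                     fixed = TRUE)[[1]]
  pw_check(grepl("^NRRD000", header[1]), "not an NRRD file",
           "protonWET_malformed_header_error")
  fields <- list()
  kv <- list()
  for (line in header[-1]) {
    if (grepl(":=", line, fixed = TRUE)) {
      parts <- strsplit(line, ":=", fixed = TRUE)[[1]]
      kv[[trimws(parts[1])]] <- trimws(parts[2])
    } else if (grepl(": ", line, fixed = TRUE)) {
      parts <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(trimws(parts[1]))]] <- trimws(parts[2])
    }
  }
  need <- c("type", "dimension", "sizes", "encoding")
  pw_check(all(need %in% names(fields)),
           "NRRD header is missing required fields",
           "protonWET_malformed_header_error")
  pw_check(fields$dimension == "3", "only 3-D NRRD grids are supported",
           "protonWET_malformed_header_error")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  pw_check(type %in% names(nrrd_type_info),
           sprintf("unsupported NRRD type '%s'", type),
           "protonWET_malformed_header_error")
  parse_vec <- function(s) as.numeric(strsplit(gsub("[(),]", " ", s), "\\s+")[[1]][-1])
  spacing <- c(1, 1, 1)
  if (!is.null(fields$`space directions`)) {
    m <- matrix(as.numeric(strsplit(gsub("[(),]", " ",
                                         fields$`space directions`),
                                    "\\s+")[[1]][-1]), nrow = 3)
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`)) origin <- parse_vec(fields$`space origin`)
  n <- prod(sizes)
  payload <- bytes[(header_end + 1L):length(bytes)]
  ti <- nrrd_type_info[[type]]
  vals <- switch(fields$encoding,
    raw = readBin(payload, ti$what, n, size = ti$size, endian = "little"),
    gzip = readBin(memDecompress(payload, type = "gzip"), ti$what, n,
                   size = ti$size, endian = "little"),
    text = as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]]),
    pw_abort(sprintf("unsupported NRRD encoding '%s'", fields$encoding),
             "protonWET_malformed_header_error")
  )
  pw_check(length(vals) == n, "NRRD payload size does not match `sizes`",
           "protonWET_shape_error")
  kind <- if (!is.null(kv$kind)) kv$kind else if (type == "uint8") "mask" else "hu"
  arr <- array(if (kind == "mask") vals != 0 else as.numeric(vals), sizes)
  vox_grid(arr, spacing, origin, kind = kind)
}

#' @rdname read_nrrd
#' @param grid a [vox_grid()] to write.
#' @param encoding payload encoding: `"gzip"` (default), `"raw"`, or
#'   `"text"`.
#' @export
write_nrrd <- function(grid, path, encoding = c("gzip", "raw", "text")) {
  pw_check(inherits(grid, "vox_grid"), "`grid` must be a vox_grid")
  encoding <- match.arg(encoding)
  d <- grid_dim(grid)
  is_mask <- grid$kind == "mask"
  type <- if (is_mask) "uint8" else "double"
  fmt_v <- function(v) paste0("(", paste(format(v, digits = 17, scientific = FALSE),
                                         collapse = ","), ")")
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("space dimension: 3"),
    paste0("space directions: ",
           paste(fmt_v(c(grid$spacing[1], 0, 0)),
                 fmt_v(c(0, grid$spacing[2], 0)),
                 fmt_v(c(0, 0, grid$spacing[3])))),
    paste0("space origin: ", fmt_v(grid$origin)),
    paste0("encoding: ", encoding),
    "endian: little",
    paste0("kind:=", grid$kind),
    ""
  )
  vals <- as.vector(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (encoding == "text") {
    writeBin(charToRaw(paste(format(vals, digits = 17, scientific = TRUE,
                                    trim = TRUE),
                             collapse = "\n")), con)
  } else {
    payload <- if (is_mask) {
      writeBin(as.integer(vals), raw(), size = 1L, endian = "little")
    } else {
      writeBin(as.double(vals), raw(), size = 8L, endian = "little")
    }
    if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
  }
  invisible(path)
}

#' Read a study configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration for
#' [run_study()]; see [default_study_config()] for the schema.
#'
#' @param path configuration file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  pw_check(file.exists(path), sprintf("file not found: %s", path),
           "protonWET_io_error")
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    pw_abort(sprintf("unsupported config extension '.%s'", ext),
             "protonWET_io_error")
  )
  cfg
}
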