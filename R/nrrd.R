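# Minimal NRRD (Nearly Raw Raster Data) reader/writer for 3D scalar volumes.
# Covers the subset of the format that tomography pipelines emit in practice:
# attached headers, raw or gzip encodings, scalar integer/float types,
# per-axis spacing via "spacings" or a diagonal "space directions", and
# "space origin". Not a general NRRD implementation.

nrrdTypeMap <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"    = list(what = "integer", size = 1, signed = TRUE),
  "uchar"   = list(what = "integer", size = 1, signed = FALSE),
  "uint8"   = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "short"   = list(what = "integer", size = 2, signed = TRUE),
  "int16"   = list(what = "integer", size = 2, signed = TRUE),
  "ushort"  = list(what = "integer", size = 2, signed = FALSE),
  "uint16"  = list(what = "integer", size = 2, signed = FALSE),
  "int"     = list(what = "integer", size = 4, signed = TRUE),
  "int32"   = list(what = "integer", size = 4, signed = TRUE),
  "uint"    = list(what = "integer", size = 4, signed = FALSE),
  "uint32"  = list(what = "integer", size = 4, signed = FALSE),
  "float"   = list(what = "numeric", size = 4, signed = TRUE),
  "double"  = list(what = "numeric", size = 8, signed = TRUE))

parseNrrdVector <- function(s) {
  s <- gsub("[()]", "", s)
  as.numeric(strsplit(trimws(s), "[, ]+")[[1]])
}

readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dimension <- as.integer(fields[["dimension"]])
  if (is.na(dimension) || dimension != 3L)
    stop("volume in ", path, " is ", dimension, "-dimensional, expected 3D")
  sizes <- as.integer(parseNrrdVector(fields[["sizes"]]))
  type <- fields[["type"]]
  spec <- nrrdTypeMap[[type]]
  if (is.null(spec)) stop("unsupported NRRD type '", type, "' in ", path)
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding '", encoding, "' in ", path)
  }
  vals <- readBin(payload, what = spec$what, n = n, size = spec$size,
                  signed = if (spec$size < 4) spec$signed else TRUE,
                  endian = endian)
  if (length(vals) < n)
    stop("truncated NRRD data in ", path, ": expected ", n, " values, got ",
         length(vals))
  spc <- NULL
  if (!is.null(fields[["spacings"]])) {
    spc <- parseNrrdVector(fields[["spacings"]])
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)",
                                fields[["space directions"]]))[[1]]
    m <- vapply(dirs, function(s) parseNrrdVector(s), numeric(3))
    spc <- sqrt(colSums(m^2))
  }
  org <- if (!is.null(fields[["space origin"]]))
    parseNrrdVector(fields[["space origin"]]) else c(0, 0, 0)
  list(data = array(as.numeric(vals), dim = sizes),
       spacing = if (is.null(spc)) NULL else spc,
       origin = org)
}

writeNrrd <- function(arr, path, spacing, origin = c(0, 0, 0),
                      encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c("NRRD0004",
           "# generated by angioscale",
           "type: double",
           "dimension: 3",
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 15),
                                      collapse = " ")),
           paste0("space origin: (", paste(format(origin, digits = 15),
                                           collapse = ","), ")"),
           "endian: little",
           paste0("encoding: ", encoding),
           "")
  writeLines(hdr, con)
  payload <- writeBin(as.numeric(arr), raw(), size = 8, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
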