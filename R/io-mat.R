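# Minimal MATLAB MAT v5 container I/O for numeric arrays.
# Layout: 128-byte header (116-byte text, 8-byte subsystem offset, version
# int16, endian indicator "IM"/"MI"), then a sequence of data elements, each
# an 8-byte tag (uint32 type, uint32 byte count) plus payload padded to an
# 8-byte boundary. Numeric arrays are miMATRIX elements holding array-flags,
# dimensions, name and real-part subelements. zlib-wrapped miCOMPRESSED
# elements are inflated with memDecompress(type = "gzip").

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L

# mxCLASS codes for numeric arrays -> the mi type their data usually carries
mat_numeric_classes <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L) # double..uint32

# internal: decode `n` values of an mi data type from raw bytes
mat_decode <- function(bytes, mitype, endian) {
  switch(as.character(mitype),
    `1` = readBin(bytes, "integer", n = length(bytes), size = 1L,
                  signed = TRUE, endian = endian),
    `2` = readBin(bytes, "integer", n = length(bytes), size = 1L,
                  signed = FALSE, endian = endian),
    `3` = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                  signed = TRUE, endian = endian),
    `4` = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                  signed = FALSE, endian = endian),
    `5` = readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                  signed = TRUE, endian = endian),
    `6` = { # uint32: readBin has no unsigned 4-byte; fix up negatives
      v <- readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                   signed = TRUE, endian = endian)
      v <- as.double(v)
      v[v < 0] <- v[v < 0] + 2^32
      v
    },
    `7` = readBin(bytes, "double", n = length(bytes) %/% 4L, size = 4L,
                  endian = endian),
    `9` = readBin(bytes, "double", n = length(bytes) %/% 8L, size = 8L,
                  endian = endian),
    stop("unsupported MAT data type mi", mitype, call. = FALSE)
  )
}

# internal: parse the element stream in `raw_data` starting at byte `pos`
# (1-based); returns named list of arrays. Recurses into compressed elements.
mat_parse_elements <- function(raw_data, pos, endian, vars = list()) {
  n_total <- length(raw_data)
  while (pos + 7L <= n_total) {
    type <- mat_decode(raw_data[pos:(pos + 3L)], MI_UINT32, endian)
    small_nbytes <- type %/% 65536
    if (small_nbytes > 0) {
      # small data element: type and data packed into 8 bytes
      pos <- pos + 8L
      next # only matrix elements matter at top level; small ones never are
    }
    nbytes <- mat_decode(raw_data[(pos + 4L):(pos + 7L)], MI_UINT32, endian)
    data_start <- pos + 8L
    payload <- if (nbytes > 0)
      raw_data[data_start:(data_start + nbytes - 1L)] else raw(0)
    if (type == MI_COMPRESSED) {
      inflated <- memDecompress(payload, type = "gzip")
      vars <- mat_parse_elements(inflated, 1L, endian, vars)
    } else if (type == MI_MATRIX) {
      v <- mat_parse_matrix(payload, endian)
      if (!is.null(v)) vars[[v$name]] <- v$value
    }
    pos <- data_start + nbytes + ((8L - nbytes %% 8L) %% 8L)
  }
  vars
}

# internal: read one subelement (handling the small-element format) from
# `bytes` at `pos`; returns list(type, data, next_pos)
mat_subelement <- function(bytes, pos, endian) {
  type <- mat_decode(bytes[pos:(pos + 3L)], MI_UINT32, endian)
  small_nbytes <- type %/% 65536
  if (small_nbytes > 0) {
    type <- type %% 65536
    data <- if (small_nbytes > 0)
      bytes[(pos + 4L):(pos + 4L + small_nbytes - 1L)] else raw(0)
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  nbytes <- mat_decode(bytes[(pos + 4L):(pos + 7L)], MI_UINT32, endian)
  data <- if (nbytes > 0)
    bytes[(pos + 8L):(pos + 8L + nbytes - 1L)] else raw(0)
  list(type = type, data = data,
       next_pos = pos + 8L + nbytes + ((8L - nbytes %% 8L) %% 8L))
}

# internal: decode a miMATRIX payload into list(name, value) or NULL for
# unsupported classes (cell/struct/char/sparse are skipped)
mat_parse_matrix <- function(bytes, endian) {
  se <- mat_subelement(bytes, 1L, endian)       # array flags (miUINT32 x2)
  flags <- mat_decode(se$data, MI_UINT32, endian)
  mxclass <- flags[1L] %% 256
  complex_flag <- bitwAnd(as.integer(flags[1L] %/% 256) , 8L) != 0L
  se2 <- mat_subelement(bytes, se$next_pos, endian)   # dimensions (miINT32)
  dims <- mat_decode(se2$data, MI_INT32, endian)
  se3 <- mat_subelement(bytes, se2$next_pos, endian)  # name (miINT8)
  name <- rawToChar(as.raw(se3$data[se3$data != as.raw(0)]))
  if (!(mxclass %in% mat_numeric_classes)) {
    return(NULL)
  }
  if (complex_flag) {
    stop("complex MAT variable '", name, "' is not supported", call. = FALSE)
  }
  se4 <- mat_subelement(bytes, se3$next_pos, endian)  # real part
  v <- mat_decode(se4$data, se4$type, endian)
  if (length(v) != prod(dims)) {
    stop("MAT variable '", name, "': payload length ", length(v),
         " does not match dims ", paste(dims, collapse = "x"), call. = FALSE)
  }
  # MATLAB stores column-major, same as R
  value <- if (length(dims) > 1L) array(v, dim = dims) else v
  list(name = name, value = value)
}

#' Read variables from a MATLAB MAT v5 file
#'
#' Reads all numeric (real, non-sparse) array variables; zlib-compressed
#' elements are supported. Character, cell, struct and sparse variables are
#' silently skipped; complex variables raise an error. HDF5-based v7.3 files
#' are detected and rejected with an explicit message.
#'
#' @param path path to the `.mat` file.
#' @param variable optional variable name; when given, that variable is
#'   returned directly instead of the full list.
#' @return a named list of arrays, or a single array if `variable` is given.
#' @export
read_mat <- function(path, variable = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw_data <- readBin(path, "raw", n = file.size(path))
  if (length(raw_data) < 128L) {
    stop("'", path, "' is too short to be a MAT v5 file", call. = FALSE)
  }
  head_txt <- rawToChar(raw_data[1:8])
  if (startsWith(head_txt, "MATLAB 7") && grepl("7\\.3", rawToChar(raw_data[1:116]))) {
    stop("'", path, "' is a MAT v7.3 (HDF5) file, which is not supported; ",
         "re-save it as v5 (e.g. scipy.io.savemat or MATLAB -v7)",
         call. = FALSE)
  }
  endian_tag <- rawToChar(raw_data[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI")
    "big" else stop("'", path, "' has no MAT v5 endian indicator",
                    call. = FALSE)
  vars <- mat_parse_elements(raw_data, 129L, endian)
  if (is.null(variable)) {
    return(vars)
  }
  if (!variable %in% names(vars)) {
    stop("variable '", variable, "' not found in ", path, "; available: ",
         paste(names(vars), collapse = ", "), call. = FALSE)
  }
  vars[[variable]]
}

# internal: serialize one full-format subelement with 8-byte padding
mat_write_subelement <- function(con, mitype, bytes) {
  writeBin(as.integer(c(mitype, length(bytes))), con, size = 4L,
           endian = "little")
  writeBin(bytes, con)
  pad <- (8L - length(bytes) %% 8L) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
}

#' Write numeric arrays to a MATLAB MAT v5 file
#'
#' Stores each variable as an uncompressed double-precision miMATRIX element,
#' so `read_mat(write_mat(...))` round-trips bit-exactly.
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  if (!is.list(vars) || is.null(names(vars)) || any(names(vars) == "")) {
    stop("vars must be a named list of numeric arrays", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by fhcdsr on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  desc_raw <- charToRaw(desc)
  header <- c(desc_raw, charToRaw(strrep(" ", 116L - length(desc_raw))))
  writeBin(header, con)
  writeBin(raw(8L), con)                                  # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)                          # little endian
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!is.numeric(v)) {
      stop("variable '", nm, "' is not numeric", call. = FALSE)
    }
    dims <- if (is.null(dim(v))) c(1L, length(v)) else dim(v)
    storage.mode(v) <- "double"
    name_raw <- charToRaw(nm)
    dims_raw <- writeBin(as.integer(dims), raw(), size = 4L,
                         endian = "little")
    data_raw <- writeBin(as.vector(v), raw(), size = 8L, endian = "little")
    sub_len <- function(nbytes) 8L + nbytes + ((8L - nbytes %% 8L) %% 8L)
    total <- sub_len(8L) + sub_len(length(dims_raw)) +
      sub_len(length(name_raw)) + sub_len(length(data_raw))
    writeBin(as.integer(c(MI_MATRIX, total)), con, size = 4L,
             endian = "little")
    # array flags: mxDOUBLE_CLASS = 6, no flags set
    mat_write_subelement(con, MI_UINT32,
                         writeBin(c(6L, 0L), raw(), size = 4L,
                                  endian = "little"))
    mat_write_subelement(con, MI_INT32, dims_raw)
    mat_write_subelement(con, MI_INT8, name_raw)
    mat_write_subelement(con, MI_DOUBLE, data_raw)
  }
  invisible(path)
}
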