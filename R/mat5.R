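# Minimal MAT v5 (Level 5 MAT-file) reader/writer.
#
# Covers the subset the HaLT recording layout needs: little-endian files,
# numeric arrays (int8..uint64, single, double), character arrays, cell
# arrays, 1x1 structs, and zlib-compressed (miCOMPRESSED) elements on read.
# Sparse, complex and logical arrays are out of scope and raise errors.

# MAT data-type (mi*) and array-class (mx*) codes
.mi <- list(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
            UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
            UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L,
            UTF8 = 16L, UTF16 = 17L)
.mx <- list(CELL = 1L, STRUCT = 2L, OBJECT = 3L, CHAR = 4L, SPARSE = 5L,
            DOUBLE = 6L, SINGLE = 7L, INT8 = 8L, UINT8 = 9L, INT16 = 10L,
            UINT16 = 11L, INT32 = 12L, UINT32 = 13L, INT64 = 14L,
            UINT64 = 15L)

.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad8 <- function(r) {
  pad <- (8L - length(r) %% 8L) %% 8L
  if (pad > 0L) c(r, raw(pad)) else r
}

# full-format tag + padded payload
.mat_element <- function(type, payload) {
  c(.u32(type), .u32(length(payload)), .pad8(payload))
}

.mat_name <- function(name) .mat_element(.mi$INT8, charToRaw(name))

.mat_numeric_payload <- function(x) {
  .mat_element(.mi$DOUBLE, writeBin(as.double(x), raw(), size = 8,
                                    endian = "little"))
}

.mat_array_flags <- function(class_code) {
  .mat_element(.mi$UINT32, c(.u32(class_code), .u32(0L)))
}

.mat_dims <- function(d) .mat_element(.mi$INT32, .u32(as.integer(d)))

# Serialize one R object as a miMATRIX element body (flags+dims+name+data)
.mat_matrix <- function(x, name = "") {
  if (is.character(x)) {
    # char matrix: one row per string, space-padded, column-major uint16
    width <- max(nchar(x), 1L)
    padded <- formatC(x, width = -width)  # left-justified, space pad
    codes <- vapply(padded, function(s) {
      v <- utf8ToInt(s)
      length(v) <- width
      v[is.na(v)] <- 32L
      v
    }, integer(width))
    m <- matrix(as.integer(codes), nrow = width)  # width x nstr
    body <- c(.mat_array_flags(.mx$CHAR),
              .mat_dims(c(length(x), width)),
              .mat_name(name),
              .mat_element(.mi$UINT16,
                           writeBin(as.integer(t(m)), raw(), size = 2,
                                    endian = "little")))
  } else if (is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))) {
    # 1x1 struct
    fields <- names(x)
    namebytes <- unlist(lapply(fields, function(f) {
      b <- charToRaw(f)
      if (length(b) > 31L) stop("field name too long: ", f)
      c(b, raw(32L - length(b)))
    }))
    nested <- unlist(lapply(x, function(el) .mat_matrix(el, name = "")))
    body <- c(.mat_array_flags(.mx$STRUCT),
              .mat_dims(c(1L, 1L)),
              .mat_name(name),
              .mat_element(.mi$INT32, .u32(32L)),
              .mat_element(.mi$INT8, namebytes),
              nested)
  } else if (is.list(x)) {
    # cell array (1 x n)
    nested <- unlist(lapply(x, function(el) .mat_matrix(el, name = "")))
    body <- c(.mat_array_flags(.mx$CELL),
              .mat_dims(c(1L, length(x))),
              .mat_name(name),
              nested)
  } else if (is.numeric(x)) {
    d <- dim(x)
    if (is.null(d)) d <- c(length(x), 1L)
    body <- c(.mat_array_flags(.mx$DOUBLE),
              .mat_dims(d),
              .mat_name(name),
              .mat_numeric_payload(x))
  } else {
    stop("unsupported type for MAT serialization: ", class(x)[1])
  }
  .mat_element(.mi$MATRIX, body)
}

#' Write variables to a MAT v5 file
#'
#' @param vars named list of variables: numeric vectors/matrices, character
#'   vectors (stored as char matrices), unnamed lists (cell arrays) or fully
#'   named lists (1x1 structs).
#' @param path output file path.
#' @return `path`, invisibly.
#' @keywords internal
mat5_write <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, created by mieegnet on %s",
    format(Sys.time(), "%Y-%m-%d")))
  length(header) <- 116L
  header[is.na(header) | header == as.raw(0)] <- as.raw(32L)
  hdr <- c(header, raw(8), writeBin(c(0x00L, 0x01L), raw(), size = 1),
           charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) .mat_matrix(vars[[nm]], nm)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, body), con)
  invisible(path)
}

# ---- reading ----

.rd_int <- function(raw, off, size, signed = TRUE, n = 1L) {
  readBin(raw[(off + 1L):(off + n * size)], "integer", n = n, size = size,
          signed = signed, endian = "little")
}

# read an element tag at offset; returns list(type, nbytes, data_off, next_off)
.mat_read_tag <- function(raw, off) {
  word1 <- .rd_int(raw, off, 4L)
  small_n <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small_n > 0L) {
    list(type = bitwAnd(word1, 0xFFFFL), nbytes = small_n,
         data_off = off + 4L, next_off = off + 8L)
  } else {
    nbytes <- .rd_int(raw, off + 4L, 4L)
    pad <- (8L - nbytes %% 8L) %% 8L
    list(type = word1, nbytes = nbytes, data_off = off + 8L,
         next_off = off + 8L + nbytes + pad)
  }
}

.mat_numeric_from <- function(raw, off, nbytes, type) {
  seg <- raw[(off + 1L):(off + nbytes)]
  switch(as.character(type),
    "1" = as.double(readBin(seg, "integer", n = nbytes, size = 1,
                            signed = TRUE)),
    "2" = as.double(readBin(seg, "integer", n = nbytes, size = 1,
                            signed = FALSE)),
    "3" = as.double(readBin(seg, "integer", n = nbytes %/% 2L, size = 2,
                            signed = TRUE, endian = "little")),
    "4" = as.double(readBin(seg, "integer", n = nbytes %/% 2L, size = 2,
                            signed = FALSE, endian = "little")),
    "5" = as.double(readBin(seg, "integer", n = nbytes %/% 4L, size = 4,
                            endian = "little")),
    "6" = {
      v <- readBin(seg, "integer", n = nbytes %/% 4L, size = 4,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.double(v))
    },
    "7" = readBin(seg, "double", n = nbytes %/% 4L, size = 4,
                  endian = "little"),
    "9" = readBin(seg, "double", n = nbytes %/% 8L, size = 8,
                  endian = "little"),
    "16" = utf8ToInt(rawToChar(seg)),
    "17" = as.double(readBin(seg, "integer", n = nbytes %/% 2L, size = 2,
                             signed = FALSE, endian = "little")),
    stop("unsupported MAT data type: ", type)
  )
}

# parse one miMATRIX payload; returns list(name, value)
.mat_parse_matrix <- function(raw, off, end) {
  # array flags
  t1 <- .mat_read_tag(raw, off)
  flags <- .rd_int(raw, t1$data_off, 4L)
  class_code <- bitwAnd(flags, 0xFFL)
  # dimensions
  t2 <- .mat_read_tag(raw, t1$next_off)
  dims <- .rd_int(raw, t2$data_off, 4L, n = t2$nbytes %/% 4L)
  # name
  t3 <- .mat_read_tag(raw, t2$next_off)
  nm <- if (t3$nbytes > 0L)
    rawToChar(raw[(t3$data_off + 1L):(t3$data_off + t3$nbytes)]) else ""
  pos <- t3$next_off

  if (class_code %in% c(.mx$DOUBLE, .mx$SINGLE, .mx$INT8, .mx$UINT8,
                        .mx$INT16, .mx$UINT16, .mx$INT32, .mx$UINT32,
                        .mx$INT64, .mx$UINT64)) {
    td <- .mat_read_tag(raw, pos)
    v <- .mat_numeric_from(raw, td$data_off, td$nbytes, td$type)
    if (length(dims) == 2L && dims[2] == 1L) dim(v) <- NULL
    else dim(v) <- dims
    list(name = nm, value = v, next_off = td$next_off)
  } else if (class_code == .mx$CHAR) {
    td <- .mat_read_tag(raw, pos)
    codes <- .mat_numeric_from(raw, td$data_off, td$nbytes, td$type)
    nrow <- dims[1]; ncol <- prod(dims) %/% max(nrow, 1L)
    if (nrow <= 1L) {
      val <- intToUtf8(codes)
    } else {
      m <- matrix(as.integer(codes), nrow = nrow)
      val <- apply(m, 1L, intToUtf8)
      val <- sub(" +$", "", val)
    }
    list(name = nm, value = val, next_off = td$next_off)
  } else if (class_code == .mx$CELL) {
    n <- prod(dims)
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      tc <- .mat_read_tag(raw, pos)
      stopifnot(tc$type == .mi$MATRIX)
      el <- .mat_parse_matrix(raw, tc$data_off, tc$next_off)
      cells[[i]] <- el$value
      pos <- tc$next_off
    }
    list(name = nm, value = cells, next_off = pos)
  } else if (class_code == .mx$STRUCT) {
    tf <- .mat_read_tag(raw, pos)          # field-name length (normally 32)
    flen <- .rd_int(raw, tf$data_off, 4L)
    tn <- .mat_read_tag(raw, tf$next_off)  # field names
    nfields <- tn$nbytes %/% flen
    fnames <- vapply(seq_len(nfields), function(i) {
      seg <- raw[(tn$data_off + (i - 1L) * flen + 1L):(tn$data_off + i * flen)]
      rawToChar(seg[seg != as.raw(0)])
    }, character(1))
    pos <- tn$next_off
    nrec <- prod(dims)
    out <- stats::setNames(vector("list", nfields), fnames)
    if (nrec != 1L) stop("only 1x1 structs are supported (got dims ",
                         paste(dims, collapse = "x"), ")")
    for (f in seq_len(nfields)) {
      tc <- .mat_read_tag(raw, pos)
      stopifnot(tc$type == .mi$MATRIX)
      el <- .mat_parse_matrix(raw, tc$data_off, tc$next_off)
      out[[f]] <- el$value
      pos <- tc$next_off
    }
    list(name = nm, value = out, next_off = pos)
  } else {
    stop("unsupported MAT array class: ", class_code)
  }
}

#' Read a MAT v5 file
#'
#' @param path MAT-file path.
#' @return named list of top-level variables.
#' @keywords internal
mat5_read <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") stop("unsupported MAT byte order or format: ", path)
  out <- list()
  pos <- 128L
  while (pos + 8L <= length(raw)) {
    tag <- .mat_read_tag(raw, pos)
    if (tag$type == .mi$COMPRESSED) {
      payload <- raw[(tag$data_off + 1L):(tag$data_off + tag$nbytes)]
      inner <- memDecompress(payload, type = "gzip")
      itag <- .mat_read_tag(inner, 0L)
      if (itag$type == .mi$MATRIX) {
        el <- .mat_parse_matrix(inner, itag$data_off, itag$next_off)
        out[[el$name]] <- el$value
      }
    } else if (tag$type == .mi$MATRIX) {
      el <- .mat_parse_matrix(raw, tag$data_off, tag$next_off)
      out[[el$name]] <- el$value
    }
    pos <- tag$next_off
  }
  out
}
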