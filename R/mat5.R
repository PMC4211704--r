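# Minimal MAT-v5 (Level 5 MAT-file) reader and writer, little-endian.
# Supports what connectivity archives actually contain: numeric arrays
# (stored as double), cell arrays, structs and character arrays, plus
# zlib-compressed elements. The writer emits uncompressed files and
# exists mainly for round-trip validation of the reader.

mi_types <- c(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
              UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
              UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L,
              UTF16 = 17L)

mx_classes <- c(CELL = 1L, STRUCT = 2L, OBJECT = 3L, CHAR = 4L, SPARSE = 5L,
                DOUBLE = 6L, SINGLE = 7L, INT8 = 8L, UINT8 = 9L, INT16 = 10L,
                UINT16 = 11L, INT32 = 12L, UINT32 = 13L, INT64 = 14L,
                UINT64 = 15L)

# --- reading ---------------------------------------------------------------

mat5_read_numeric <- function(buf, pos, type, nbytes) {
  le <- "little"
  switch(as.character(type),
    "1" = readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes, size = 1,
                  signed = TRUE, endian = le),
    "2" = readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes, size = 1,
                  signed = FALSE, endian = le),
    "3" = readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes / 2, size = 2,
                  signed = TRUE, endian = le),
    "4" = readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes / 2, size = 2,
                  signed = FALSE, endian = le),
    "5" = readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes / 4, size = 4,
                  endian = le),
    "6" = {
      v <- readBin(buf[pos:(pos + nbytes - 1)], "integer", nbytes / 4,
                   size = 4, endian = le)
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = readBin(buf[pos:(pos + nbytes - 1)], "double", nbytes / 4, size = 4,
                  endian = le),
    "9" = readBin(buf[pos:(pos + nbytes - 1)], "double", nbytes / 8, size = 8,
                  endian = le),
    "16" = rawToChar(buf[pos:(pos + nbytes - 1)]),
    "17" = intToUtf8(readBin(buf[pos:(pos + nbytes - 1)], "integer",
                             nbytes / 2, size = 2, signed = FALSE,
                             endian = le), multiple = FALSE),
    stop("unsupported MAT data type: ", type)
  )
}

# Read the tag at `pos`; returns list(type, nbytes, data_pos, next_pos).
mat5_read_tag <- function(buf, pos) {
  word <- readBin(buf[pos:(pos + 3)], "integer", 1, size = 4,
                  endian = "little")
  small <- bitwAnd(word, -65536L) != 0L   # high 16 bits nonzero
  if (small) {
    type <- bitwAnd(word, 65535L)
    nbytes <- bitwShiftR(bitwAnd(word, -65536L), 16)
    list(type = type, nbytes = nbytes, data_pos = pos + 4,
         next_pos = pos + 8)
  } else {
    nbytes <- readBin(buf[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                      endian = "little")
    pad <- if (type_is_matrix_or_compressed(word)) 0 else (8 - nbytes %% 8) %% 8
    list(type = word, nbytes = nbytes, data_pos = pos + 8,
         next_pos = pos + 8 + nbytes + pad)
  }
}

type_is_matrix_or_compressed <- function(type) {
  type %in% c(mi_types[["MATRIX"]], mi_types[["COMPRESSED"]])
}

# Parse one miMATRIX payload (buf slice spanning exactly the element).
mat5_parse_matrix <- function(buf, pos, end) {
  if (pos > end) return(NULL)              # empty element
  tag <- mat5_read_tag(buf, pos)           # array flags (miUINT32 x2)
  flags <- readBin(buf[tag$data_pos:(tag$data_pos + 7)], "integer", 2,
                   size = 4, endian = "little")
  cls <- bitwAnd(flags[1], 255L)
  pos <- tag$next_pos

  tag <- mat5_read_tag(buf, pos)           # dimensions (miINT32)
  dims <- mat5_read_numeric(buf, tag$data_pos, tag$type, tag$nbytes)
  pos <- tag$next_pos

  tag <- mat5_read_tag(buf, pos)           # name (miINT8)
  name <- if (tag$nbytes > 0) {
    rawToChar(buf[tag$data_pos:(tag$data_pos + tag$nbytes - 1)])
  } else ""
  pos <- tag$next_pos

  value <- if (cls == mx_classes[["CELL"]]) {
    nel <- prod(dims)
    items <- vector("list", nel)
    for (k in seq_len(nel)) {
      tag <- mat5_read_tag(buf, pos)
      if (tag$type != mi_types[["MATRIX"]]) stop("malformed cell array")
      sub <- mat5_parse_matrix(buf, tag$data_pos,
                               tag$data_pos + tag$nbytes - 1)
      items[[k]] <- if (is.null(sub)) NULL else sub$value
      pos <- tag$data_pos + tag$nbytes + (8 - tag$nbytes %% 8) %% 8
    }
    if (length(dims) > 2 || dims[1] > 1) attr(items, "mat_dim") <- dims
    items
  } else if (cls == mx_classes[["STRUCT"]]) {
    tag <- mat5_read_tag(buf, pos)         # field name length
    flen <- mat5_read_numeric(buf, tag$data_pos, tag$type, tag$nbytes)[1]
    pos <- tag$next_pos
    tag <- mat5_read_tag(buf, pos)         # field names
    nf <- tag$nbytes / flen
    fnames <- vapply(seq_len(nf), function(k) {
      raw_name <- buf[(tag$data_pos + (k - 1) * flen):
                        (tag$data_pos + k * flen - 1)]
      rawToChar(raw_name[raw_name != as.raw(0)])
    }, character(1))
    pos <- tag$next_pos
    fields <- vector("list", nf)
    names(fields) <- fnames
    for (k in seq_len(nf)) {
      tag <- mat5_read_tag(buf, pos)
      sub <- mat5_parse_matrix(buf, tag$data_pos,
                               tag$data_pos + tag$nbytes - 1)
      fields[[k]] <- if (is.null(sub)) NULL else sub$value
      pos <- tag$data_pos + tag$nbytes + (8 - tag$nbytes %% 8) %% 8
    }
    fields
  } else if (cls == mx_classes[["CHAR"]]) {
    tag <- mat5_read_tag(buf, pos)
    txt <- mat5_read_numeric(buf, tag$data_pos, tag$type, tag$nbytes)
    if (is.numeric(txt)) txt <- intToUtf8(txt, multiple = FALSE)
    txt
  } else if (cls %in% mx_classes[c("DOUBLE", "SINGLE", "INT8", "UINT8",
                                   "INT16", "UINT16", "INT32", "UINT32")]) {
    tag <- mat5_read_tag(buf, pos)
    v <- as.numeric(mat5_read_numeric(buf, tag$data_pos, tag$type,
                                      tag$nbytes))
    if (length(dims) == 2 && (dims[1] == 1 || dims[2] == 1)) {
      v                                     # row/column vectors and scalars
    } else {
      array(v, dim = dims)
    }
  } else {
    stop("unsupported MAT array class: ", cls)
  }
  list(name = name, value = value)
}

#' Read a MAT-v5 file
#'
#' Reads little-endian Level 5 MAT-files, including zlib-compressed
#' elements. Numeric arrays become R arrays of doubles, cell arrays
#' become lists, structs become named lists, character arrays become
#' strings. Sparse arrays and MAT-v7.3 (HDF5) files are not supported.
#'
#' @param path file path.
#' @return named list of the file's variables.
#' @export
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 128) stop("not a MAT-v5 file: ", path)
  endian <- rawToChar(buf[127:128])
  if (endian == "MI") {
    stop("big-endian MAT files are not supported")
  } else if (endian != "IM") {
    stop("not a MAT-v5 file (bad endian indicator): ", path)
  }
  pos <- 129
  out <- list()
  while (pos + 7 <= length(buf)) {
    tag <- mat5_read_tag(buf, pos)
    if (tag$type == mi_types[["COMPRESSED"]]) {
      inner <- memDecompress(buf[tag$data_pos:(tag$data_pos + tag$nbytes - 1)],
                             type = "gzip")
      itag <- mat5_read_tag(inner, 1)
      if (itag$type != mi_types[["MATRIX"]]) {
        stop("unexpected element inside compressed block: ", itag$type)
      }
      el <- mat5_parse_matrix(inner, itag$data_pos,
                              itag$data_pos + itag$nbytes - 1)
    } else if (tag$type == mi_types[["MATRIX"]]) {
      el <- mat5_parse_matrix(buf, tag$data_pos,
                              tag$data_pos + tag$nbytes - 1)
    } else {
      stop("unexpected top-level element type: ", tag$type)
    }
    if (!is.null(el)) out[[el$name]] <- el$value
    # compressed element payloads are not padded; uncompressed miMATRIX
    # payloads are already a multiple of 8 bytes
    pad <- if (tag$type == mi_types[["COMPRESSED"]]) 0 else
      (8 - tag$nbytes %% 8) %% 8
    pos <- tag$data_pos + tag$nbytes + pad
  }
  out
}

# --- writing ---------------------------------------------------------------

mat5_pad8 <- function(r) {
  pad <- (8 - length(r) %% 8) %% 8
  c(r, raw(pad))
}

mat5_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat5_elem_double <- function(v) {
  d <- writeBin(as.numeric(v), raw(), size = 8, endian = "little")
  mat5_pad8(c(mat5_tag(mi_types[["DOUBLE"]], length(d)), d))
}

mat5_elem_int32 <- function(v) {
  d <- writeBin(as.integer(v), raw(), size = 4, endian = "little")
  mat5_pad8(c(mat5_tag(mi_types[["INT32"]], length(d)), d))
}

mat5_elem_int8 <- function(r) {
  mat5_pad8(c(mat5_tag(mi_types[["INT8"]], length(r)), r))
}

mat5_matrix_element <- function(name, value) {
  if (is.list(value)) {
    dims <- attr(value, "mat_dim")
    if (is.null(dims)) dims <- c(1L, length(value))
    body <- unlist(lapply(value, function(v) mat5_matrix_element("", v)))
    cls <- mx_classes[["CELL"]]
  } else if (is.character(value)) {
    codes <- utf8ToInt(value)
    d <- writeBin(as.integer(codes), raw(), size = 2, endian = "little")
    body <- mat5_pad8(c(mat5_tag(mi_types[["UINT16"]], length(d)), d))
    dims <- c(1L, length(codes))
    cls <- mx_classes[["CHAR"]]
  } else {
    dims <- dim(value)
    if (is.null(dims)) dims <- c(1L, length(value))
    body <- mat5_elem_double(as.numeric(value))
    cls <- mx_classes[["DOUBLE"]]
  }
  flags <- c(writeBin(as.integer(cls), raw(), size = 4, endian = "little"),
             writeBin(0L, raw(), size = 4, endian = "little"))
  payload <- c(
    c(mat5_tag(mi_types[["UINT32"]], 8L), flags),
    mat5_elem_int32(dims),
    if (nchar(name) > 0) mat5_elem_int8(charToRaw(name)) else mat5_tag(1L, 0L),
    body
  )
  c(mat5_tag(mi_types[["MATRIX"]], length(payload)), payload)
}

#' Write a MAT-v5 file
#'
#' Writes numeric arrays (as doubles), lists (as cell arrays; an
#' optional `mat_dim` attribute sets the cell shape) and strings.
#' Output is uncompressed little-endian MAT-v5.
#'
#' @param vars named list of variables.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  txt <- "MATLAB 5.0 MAT-file, written by connstab"
  header <- charToRaw(txt)
  header <- c(header, rep(as.raw(0x20), 116 - length(header)))
  header <- c(header, raw(8))                              # subsys offset
  header <- c(header, writeBin(256L, raw(), size = 2, endian = "little"))
  header <- c(header, charToRaw("IM"))
  body <- unlist(lapply(names(vars), function(nm) {
    mat5_matrix_element(nm, vars[[nm]])
  }))
  writeBin(c(header, body), path)
  invisible(path)
}
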