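# Point-cloud file I/O: PLY (ascii / binary_little_endian), PCD (ascii /
# binary), plain XYZ text. Coordinates are meters and pass through unchanged.
# Semantic labels round-trip as an integer scalar field.

.label_levels <- c("ground", "trunk", "branch", "other")

.labels_to_int <- function(labels) match(labels, .label_levels) - 1L

.int_to_labels <- function(code) {
  out <- .label_levels[clamp(as.integer(round(code)), 0L, 3L) + 1L]
  out[is.na(code)] <- "other"
  out
}

.ply_types <- list(
  char   = list(size = 1L, what = "integer", signed = TRUE),
  int8   = list(size = 1L, what = "integer", signed = TRUE),
  uchar  = list(size = 1L, what = "integer", signed = FALSE),
  uint8  = list(size = 1L, what = "integer", signed = FALSE),
  short  = list(size = 2L, what = "integer", signed = TRUE),
  int16  = list(size = 2L, what = "integer", signed = TRUE),
  ushort = list(size = 2L, what = "integer", signed = FALSE),
  uint16 = list(size = 2L, what = "integer", signed = FALSE),
  int    = list(size = 4L, what = "integer", signed = TRUE),
  int32  = list(size = 4L, what = "integer", signed = TRUE),
  uint   = list(size = 4L, what = "integer", signed = TRUE),  # wrap fixed below
  uint32 = list(size = 4L, what = "integer", signed = TRUE),
  float  = list(size = 4L, what = "double", signed = TRUE),
  float32 = list(size = 4L, what = "double", signed = TRUE),
  double = list(size = 8L, what = "double", signed = TRUE),
  float64 = list(size = 8L, what = "double", signed = TRUE)
)

#' Read a point cloud from disk
#'
#' Supported formats: PLY (`ascii` and `binary_little_endian` dialects; the
#' rare big-endian dialect is rejected with a clear error), PCD (`ascii` and
#' `binary` data, uncompressed) and whitespace-delimited XYZ text (three
#' leading floats per line, extra columns ignored, `#` comment lines
#' skipped). Unknown per-point attributes are ignored; integer fields named
#' `label` (or `scalar_label`) and `branch_id` are restored as cloud
#' metadata. No unit conversion is ever applied.
#'
#' @param path file to read.
#' @param format one of `"auto"` (from the extension), `"ply"`, `"pcd"`,
#'   `"xyz"`.
#' @return A [point_cloud()] with points in file order.
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_treereg(paste0("file not found: ", path), "treereg_io_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                     stop_treereg(paste0("cannot detect format from extension: ", path),
                                  "treereg_io_error"))
  }
  switch(format,
         ply = .read_ply(path),
         pcd = .read_pcd(path),
         xyz = .read_xyz(path))
}

#' Write a point cloud to disk
#'
#' Labels and branch ids, when present, are emitted as extra integer scalar
#' fields so they survive a round trip through [read_cloud()]. Binary PLY and
#' PCD store coordinates as 8-byte doubles, making the round trip bit-exact.
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format `"ply"`, `"pcd"` or `"xyz"` (default: from the extension).
#' @param binary write the binary dialect (PLY/PCD only).
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("auto", "ply", "pcd", "xyz"),
                        binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", xyz = "xyz", txt = "xyz",
                     stop_treereg(paste0("cannot detect format from extension: ", path),
                                  "treereg_io_error"))
  }
  ok <- tryCatch({
    suppressWarnings(switch(format,
           ply = .write_ply(cloud, path, binary),
           pcd = .write_pcd(cloud, path, binary),
           xyz = .write_xyz(cloud, path)))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_treereg(paste0("cannot write ", path, ": ", conditionMessage(ok)),
                 "treereg_io_error")
  invisible(path)
}

# ---- XYZ ---------------------------------------------------------------

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(point_cloud(matrix(0, 0, 3)))
  toks <- strsplit(trimws(lines), "[ \t,]+")
  lens <- lengths(toks)
  if (any(lens < 3))
    stop_treereg(sprintf("malformed XYZ record at line %d: fewer than 3 columns",
                         lineno[which(lens < 3)[1]]), "treereg_parse_error")
  grab <- function(j) suppressWarnings(as.numeric(vapply(toks, `[`, "", j)))
  P <- cbind(grab(1), grab(2), grab(3))
  if (anyNA(P))
    stop_treereg(sprintf("non-numeric coordinate at line %d",
                         lineno[which(rowSums(is.na(P)) > 0)[1]]),
                 "treereg_parse_error")
  labels <- branch_id <- NULL
  if (all(lens >= 4)) {
    v <- grab(4)
    if (!anyNA(v)) labels <- .int_to_labels(v)
  }
  if (all(lens >= 5)) {
    v <- grab(5)
    if (!anyNA(v)) { branch_id <- as.integer(v); branch_id[branch_id < 0] <- NA }
  }
  point_cloud(P, labels = labels, branch_id = branch_id)
}

.write_xyz <- function(cloud, path) {
  P <- cloud$points
  cols <- list(sprintf("%.10g", P[, 1]), sprintf("%.10g", P[, 2]),
               sprintf("%.10g", P[, 3]))
  if (!is.null(cloud$labels)) {
    cols <- c(cols, list(sprintf("%d", .labels_to_int(cloud$labels))))
    if (!is.null(cloud$branch_id)) {
      bid <- cloud$branch_id
      bid[is.na(bid)] <- -1L
      cols <- c(cols, list(sprintf("%d", bid)))
    }
  }
  writeLines(do.call(paste, cols), path)
}

# ---- PLY ---------------------------------------------------------------

# Byte-level header split: find `marker` (+ trailing newline) in the raw
# file without ever converting binary payload to character.
.split_header <- function(raw, marker) {
  m <- grepRaw(paste0(marker, "\r\n"), raw, fixed = TRUE)
  len <- nchar(marker) + 2L
  if (length(m) == 0) {
    m <- grepRaw(paste0(marker, "\n"), raw, fixed = TRUE)
    len <- nchar(marker) + 1L
  }
  if (length(m) == 0) return(NULL)
  n <- m[1] + len - 1L
  list(text = rawToChar(raw[seq_len(n)]), nbytes = n)
}

.payload_after <- function(raw, nbytes) {
  if (nbytes < length(raw)) raw[(nbytes + 1L):length(raw)] else raw(0)
}

.read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  hd <- .split_header(raw, "end_header")
  if (is.null(hd))
    stop_treereg("PLY header has no end_header line", "treereg_parse_error")
  header_nbytes <- hd$nbytes
  header <- strsplit(hd$text, "\r?\n")[[1]]
  if (length(header) == 0 || trimws(header[1]) != "ply")
    stop_treereg("not a PLY file (missing 'ply' magic, line 1)", "treereg_parse_error")
  fmt <- NULL
  elements <- list()
  for (i in seq_along(header)[-1]) {
    tk <- strsplit(trimws(header[i]), "[ \t]+")[[1]]
    if (length(tk) == 0 || tk[1] %in% c("comment", "obj_info", "end_header", ""))
      next
    if (tk[1] == "format") {
      if (tk[2] == "binary_big_endian")
        stop_treereg("big-endian PLY is not supported; convert to ascii or binary_little_endian",
                     "treereg_parse_error")
      if (!tk[2] %in% c("ascii", "binary_little_endian"))
        stop_treereg(paste0("unknown PLY format '", tk[2], "' (line ", i, ")"),
                     "treereg_parse_error")
      fmt <- tk[2]
    } else if (tk[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tk[2], count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property") {
      if (length(elements) == 0)
        stop_treereg(paste0("property before any element (line ", i, ")"),
                     "treereg_parse_error")
      e <- length(elements)
      if (tk[2] == "list") {
        elements[[e]]$props[[length(elements[[e]]$props) + 1L]] <-
          list(name = tk[5], type = NA, list = TRUE)
      } else {
        if (is.null(.ply_types[[tk[2]]]))
          stop_treereg(paste0("unknown PLY property type '", tk[2], "' (line ", i, ")"),
                       "treereg_parse_error")
        elements[[e]]$props[[length(elements[[e]]$props) + 1L]] <-
          list(name = tk[3], type = tk[2], list = FALSE)
      }
    }
  }
  if (is.null(fmt)) stop_treereg("PLY header has no format line", "treereg_parse_error")
  vi <- which(vapply(elements, function(e) e$name == "vertex", TRUE))
  if (length(vi) != 1)
    stop_treereg("PLY file must contain exactly one 'vertex' element", "treereg_parse_error")
  vert <- elements[[vi]]
  if (any(vapply(vert$props, `[[`, TRUE, "list")))
    stop_treereg("list properties in the vertex element are not supported",
                 "treereg_parse_error")
  pnames <- vapply(vert$props, `[[`, "", "name")
  if (!all(c("x", "y", "z") %in% pnames))
    stop_treereg("vertex element lacks x/y/z properties", "treereg_parse_error")

  if (fmt == "ascii") {
    pay <- .payload_after(raw, header_nbytes)
    body <- if (length(pay)) strsplit(rawToChar(pay), "\r?\n")[[1]] else character(0)
    body <- body[nzchar(trimws(body))]
    cursor <- 0L
    cols <- NULL
    for (e in elements) {
      if (e$name == "vertex") {
        if (length(body) - cursor < e$count)
          stop_treereg(sprintf(
            "PLY declares %d vertex records but only %d data lines remain (after line %d of the body)",
            e$count, length(body) - cursor, cursor), "treereg_parse_error")
        lines <- body[cursor + seq_len(e$count)]
        toks <- strsplit(trimws(lines), "[ \t]+")
        np <- length(vert$props)
        lens <- lengths(toks)
        if (any(lens < np))
          stop_treereg(sprintf("truncated vertex record at body line %d",
                               cursor + which(lens < np)[1]), "treereg_parse_error")
        cols <- lapply(seq_len(np), function(j)
          suppressWarnings(as.numeric(vapply(toks, `[`, "", j))))
        if (anyNA(unlist(cols)))
          stop_treereg("non-numeric value in vertex records", "treereg_parse_error")
        cursor <- cursor + e$count
      } else {
        if (length(body) - cursor < e$count)
          stop_treereg(sprintf("element '%s' truncated in data section", e$name),
                       "treereg_parse_error")
        cursor <- cursor + e$count
      }
    }
  } else {
    payload <- .payload_after(raw, header_nbytes)
    offset <- 0L
    cols <- NULL
    for (e in elements) {
      is_list <- vapply(e$props, `[[`, TRUE, "list")
      if (any(is_list)) {
        if (e$name == "vertex" || is.null(cols))
          stop_treereg(paste0("binary PLY element '", e$name,
                              "' has list properties and cannot be skipped"),
                       "treereg_parse_error")
        break  # vertex already read; ignore trailing variable-size elements
      }
      sizes <- vapply(e$props, function(p) .ply_types[[p$type]]$size, 1L)
      rec <- sum(sizes)
      need <- rec * e$count
      if (length(payload) - offset < need)
        stop_treereg(sprintf(
          "binary PLY element '%s' truncated: need %d bytes at offset %d, have %d",
          e$name, need, offset, length(payload) - offset), "treereg_parse_error")
      if (e$name == "vertex") {
        cols <- .unpack_columns(payload[offset + seq_len(need)], e$props, sizes,
                                e$count, .ply_types)
      }
      offset <- offset + need
    }
  }
  .assemble_cloud(cols, pnames)
}

# Deinterleave one fixed-size binary record block into per-property columns.
.unpack_columns <- function(bytes, props, sizes, n, typemap) {
  rec <- sum(sizes)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  lapply(seq_along(props), function(j) {
    tp <- typemap[[props[[j]]$type]]
    sel <- as.vector(outer(seq_len(sizes[j]), (seq_len(n) - 1L) * rec + offs[j], `+`))
    v <- readBin(bytes[sel], what = tp$what, size = sizes[j], n = n,
                 signed = if (sizes[j] < 4) tp$signed else TRUE,
                 endian = "little")
    if (props[[j]]$type %in% c("uint", "uint32")) {
      v <- as.numeric(v)
      v[v < 0] <- v[v < 0] + 2^32
    }
    as.numeric(v)
  })
}

.assemble_cloud <- function(cols, pnames) {
  P <- cbind(cols[[match("x", pnames)]], cols[[match("y", pnames)]],
             cols[[match("z", pnames)]])
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  labels <- branch_id <- NULL
  li <- match(c("label", "scalar_label"), pnames)
  li <- li[!is.na(li)][1]
  if (!is.na(li)) labels <- .int_to_labels(cols[[li]])
  bi <- match("branch_id", pnames)
  if (!is.na(bi)) {
    branch_id <- as.integer(cols[[bi]])
    branch_id[branch_id < 0] <- NA
  }
  point_cloud(P, labels = labels, branch_id = branch_id)
}

.write_ply <- function(cloud, path, binary) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  has_bid <- !is.null(cloud$branch_id)
  header <- c("ply",
              paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              if (has_lab) "property int label",
              if (has_bid) "property int branch_id",
              "end_header")
  lab <- if (has_lab) .labels_to_int(cloud$labels)
  bid <- if (has_bid) { b <- cloud$branch_id; b[is.na(b)] <- -1L; b }
  if (!binary) {
    cols <- list(sprintf("%.17g", cloud$points[, 1]),
                 sprintf("%.17g", cloud$points[, 2]),
                 sprintf("%.17g", cloud$points[, 3]))
    if (has_lab) cols <- c(cols, list(sprintf("%d", lab)))
    if (has_bid) cols <- c(cols, list(sprintf("%d", bid)))
    writeLines(c(header, if (n > 0) do.call(paste, cols)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (n > 0) {
      xyz <- writeBin(as.vector(t(cloud$points)), raw(), size = 8, endian = "little")
      blocks <- list(matrix(xyz, nrow = 24L))
      if (has_lab) blocks <- c(blocks, list(matrix(writeBin(as.integer(lab), raw(),
                               size = 4, endian = "little"), nrow = 4L)))
      if (has_bid) blocks <- c(blocks, list(matrix(writeBin(as.integer(bid), raw(),
                               size = 4, endian = "little"), nrow = 4L)))
      writeBin(as.vector(do.call(rbind, blocks)), con)
    }
  }
}

# ---- PCD ---------------------------------------------------------------

.read_pcd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  dm <- grepRaw("DATA ", raw, fixed = TRUE)
  if (length(dm) == 0)
    stop_treereg("PCD header has no DATA line", "treereg_parse_error")
  nl <- grepRaw("\n", raw, offset = dm[1], fixed = TRUE)
  if (length(nl) == 0)
    stop_treereg("PCD DATA line is not newline-terminated", "treereg_parse_error")
  header_nbytes <- nl[1]
  header <- strsplit(rawToChar(raw[seq_len(header_nbytes)]), "\r?\n")[[1]]
  kv <- list()
  for (i in seq_along(header)) {
    ln <- trimws(header[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tk <- strsplit(ln, "[ \t]+")[[1]]
    kv[[tk[1]]] <- tk[-1]
  }
  for (need in c("FIELDS", "SIZE", "TYPE", "POINTS", "DATA"))
    if (is.null(kv[[need]]))
      stop_treereg(paste0("PCD header lacks ", need, " line"), "treereg_parse_error")
  fields <- kv$FIELDS
  sizes <- as.integer(kv$SIZE)
  types <- kv$TYPE
  counts <- if (!is.null(kv$COUNT)) as.integer(kv$COUNT) else rep(1L, length(fields))
  if (any(counts != 1L))
    stop_treereg("PCD COUNT > 1 is not supported", "treereg_parse_error")
  n <- as.integer(kv$POINTS[1])
  mode <- kv$DATA[1]
  if (!all(c("x", "y", "z") %in% fields))
    stop_treereg("PCD lacks x/y/z fields", "treereg_parse_error")
  if (mode == "ascii") {
    pay <- .payload_after(raw, header_nbytes)
    body <- if (length(pay)) strsplit(rawToChar(pay), "\r?\n")[[1]] else character(0)
    body <- body[nzchar(trimws(body))]
    if (length(body) < n)
      stop_treereg(sprintf("PCD declares %d points but has %d data lines",
                           n, length(body)), "treereg_parse_error")
    toks <- strsplit(trimws(body[seq_len(n)]), "[ \t]+")
    lens <- lengths(toks)
    if (any(lens < length(fields)))
      stop_treereg(sprintf("truncated PCD record at data line %d",
                           which(lens < length(fields))[1]), "treereg_parse_error")
    cols <- lapply(seq_along(fields), function(j)
      suppressWarnings(as.numeric(vapply(toks, `[`, "", j))))
    if (anyNA(unlist(cols)))
      stop_treereg("non-numeric value in PCD records", "treereg_parse_error")
  } else if (mode == "binary") {
    props <- lapply(seq_along(fields), function(j) {
      tp <- switch(types[j],
                   F = if (sizes[j] == 8) "double" else "float",
                   I = switch(as.character(sizes[j]), "1" = "char", "2" = "short", "int"),
                   U = switch(as.character(sizes[j]), "1" = "uchar", "2" = "ushort", "uint"),
                   stop_treereg(paste0("unknown PCD TYPE ", types[j]), "treereg_parse_error"))
      list(name = fields[j], type = tp, list = FALSE)
    })
    need <- sum(sizes) * n
    payload <- .payload_after(raw, header_nbytes)
    if (length(payload) < need)
      stop_treereg(sprintf("binary PCD truncated: need %d bytes, have %d",
                           need, length(payload)), "treereg_parse_error")
    cols <- .unpack_columns(payload[seq_len(need)], props, sizes, n, .ply_types)
  } else {
    stop_treereg(paste0("PCD DATA mode '", mode, "' is not supported"),
                 "treereg_parse_error")
  }
  .assemble_cloud(cols, fields)
}

.write_pcd <- function(cloud, path, binary) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  has_bid <- !is.null(cloud$branch_id)
  fields <- c("x", "y", "z", if (has_lab) "label", if (has_bid) "branch_id")
  sizes <- c(8L, 8L, 8L, if (has_lab) 4L, if (has_bid) 4L)
  types <- c("F", "F", "F", if (has_lab) "I", if (has_bid) "I")
  header <- c("# .PCD v0.7 - Point Cloud Data file format",
              "VERSION 0.7",
              paste("FIELDS", paste(fields, collapse = " ")),
              paste("SIZE", paste(sizes, collapse = " ")),
              paste("TYPE", paste(types, collapse = " ")),
              paste("COUNT", paste(rep(1L, length(fields)), collapse = " ")),
              paste("WIDTH", n), "HEIGHT 1", "VIEWPOINT 0 0 0 1 0 0 0",
              paste("POINTS", n),
              paste("DATA", if (binary) "binary" else "ascii"))
  lab <- if (has_lab) .labels_to_int(cloud$labels)
  bid <- if (has_bid) { b <- cloud$branch_id; b[is.na(b)] <- -1L; b }
  if (!binary) {
    cols <- list(sprintf("%.17g", cloud$points[, 1]),
                 sprintf("%.17g", cloud$points[, 2]),
                 sprintf("%.17g", cloud$points[, 3]))
    if (has_lab) cols <- c(cols, list(sprintf("%d", lab)))
    if (has_bid) cols <- c(cols, list(sprintf("%d", bid)))
    writeLines(c(header, if (n > 0) do.call(paste, cols)), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (n > 0) {
      xyz <- writeBin(as.vector(t(cloud$points)), raw(), size = 8, endian = "little")
      blocks <- list(matrix(xyz, nrow = 24L))
      if (has_lab) blocks <- c(blocks, list(matrix(writeBin(as.integer(lab), raw(),
                               size = 4, endian = "little"), nrow = 4L)))
      if (has_bid) blocks <- c(blocks, list(matrix(writeBin(as.integer(bid), raw(),
                               size = 4, endian = "little"), nrow = 4L)))
      writeBin(as.vector(do.call(rbind, blocks)), con)
    }
  }
}
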