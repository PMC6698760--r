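# Minimal NRRD (nearly raw raster data) reader/writer for 3-D volumes:
# NRRD0004 text header + attached raw little-endian data. Covers exactly the
# fields the portable plan format needs (no compression, no detached data).

#' Write a 3-D array to an NRRD file
#'
#' @param arr numeric or logical array (logical is stored as uint8).
#' @param grid the [volume_grid()] the array lives on.
#' @param path output path.
#' @export
write_nrrd <- function(arr, grid, path) {
  if (!identical(dim(arr), as.integer(grid$shape)))
    kb_stop("geometry_error", "array dim does not match grid shape")
  is_mask <- is.logical(arr)
  type <- if (is_mask) "uint8" else "double"
  header <- c(
    "NRRD0004",
    "# generated by kbdvh",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(grid$shape, collapse = " ")),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            grid$spacing[1], grid$spacing[2], grid$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            grid$origin[1], grid$origin[2], grid$origin[3])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n\n")), con)
  if (is_mask) {
    writeBin(as.raw(as.integer(arr)), con)
  } else {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD file written by [write_nrrd()]
#'
#' @param path NRRD file path.
#' @return list with `arr` (array; logical for uint8, numeric for double) and
#'   `grid` ([volume_grid()]).
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) kb_stop("io_error", "NRRD file not found: %s", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line (\n\n)
  sep <- which(bytes[-length(bytes)] == as.raw(10) & bytes[-1] == as.raw(10))
  if (length(sep) == 0) kb_stop("format_error", "no header/data separator in %s", path)
  sep <- sep[1]
  lines <- strsplit(rawToChar(bytes[seq_len(sep - 1)]), "\n", fixed = TRUE)[[1]]
  data_raw <- bytes[(sep + 2):length(bytes)]
  if (!grepl("^NRRD", lines[1])) kb_stop("format_error", "not an NRRD file: %s", path)
  fields <- list()
  for (ln in lines[-1]) {
    if (startsWith(ln, "#")) next
    kv <- regmatches(ln, regexec("^([^:]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[kv[2]]] <- kv[3]
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  if (!identical(fields$encoding, "raw"))
    kb_stop("format_error", "unsupported NRRD encoding '%s'", fields$encoding)
  nums <- function(s) as.numeric(regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- nums(fields$`space directions`)
  spacing <- c(dirs[1], dirs[5], dirs[9])
  origin <- nums(fields$`space origin`)
  n <- prod(sizes)
  type <- fields$type
  arr <- if (identical(type, "uint8")) {
    array(as.integer(data_raw[seq_len(n)]) > 0, dim = sizes)
  } else if (identical(type, "double")) {
    array(readBin(data_raw, "numeric", n = n, size = 8L, endian = "little"),
          dim = sizes)
  } else kb_stop("format_error", "unsupported NRRD type '%s'", type)
  list(arr = arr, grid = volume_grid(sizes, spacing, origin))
}
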