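# Minimal DICOM-RT support: an explicit-VR little-endian writer/reader pair
# covering exactly the RT Structure Set and RT Dose subset this package
# exchanges (closed planar contours; a rectilinear uint16 dose grid with
# scaling). This is a portability shim, not a general DICOM implementation:
# files it writes, it reads back losslessly; foreign files must be explicit
# VR little endian with defined sequence lengths.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_ROOT <- "1.2.826.0.1.3680043.9.7435"  # generated-UID prefix

long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# One data element as raw bytes (explicit VR little endian, defined length).
dcm_elem <- function(group, elem, vr, value) {
  body <- if (vr %in% c("UI", "SH", "CS", "LO", "DS", "IS", "DA", "TM", "PN", "ST")) {
    s <- paste(value, collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1)
      b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    b
  } else if (vr == "US") {
    dcm_uint16(value)
  } else if (vr == "OW") {
    value  # raw, caller-prepared, even length
  } else if (vr == "SQ") {
    # value: list of item datasets (each a raw vector)
    do.call(c, c(list(raw(0)), lapply(value, function(item)
      c(dcm_uint16(c(0xFFFE, 0xE000)), dcm_uint32(length(item)), item))))
  } else kb_stop("format_error", "unsupported VR '%s'", vr)
  head <- c(dcm_uint16(c(group, elem)), charToRaw(vr))
  if (vr %in% long_vrs) {
    c(head, as.raw(c(0, 0)), dcm_uint32(length(body)), body)
  } else {
    if (length(body) > 65534) kb_stop("format_error", "element too long for short VR")
    c(head, dcm_uint16(length(body)), body)
  }
}

# DS-format numbers: <= 16 bytes per value as DICOM requires.
dcm_ds <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16)) s <- sprintf("%.8g", x)
  s
}

dcm_uid <- function(...) paste(UID_ROOT, ..., sep = ".")

# Assemble a DICOM Part-10 file: preamble, DICM magic, file meta group
# (group 0002, itself explicit VR LE), then the dataset elements.
dcm_file <- function(sop_class, sop_instance, dataset_raw, path) {
  meta <- c(dcm_elem(0x0002, 0x0002, "UI", sop_class),
            dcm_elem(0x0002, 0x0003, "UI", sop_instance),
            dcm_elem(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE))
  meta <- c(dcm_elem_ul(0x0002, 0x0000, length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}

# group length element (UL) — only used for group 0002
dcm_elem_ul <- function(group, elem, value) {
  c(dcm_uint16(c(group, elem)), charToRaw("UL"), dcm_uint16(4L), dcm_uint32(value))
}

#' Export structure masks as a DICOM RT Structure Set
#'
#' Per-slice closed planar contours are reconstructed from each mask's voxel
#' boundary (rectilinear polygons along voxel edges), so rasterizing the
#' written contours back onto the same grid reproduces the masks
#' voxel-exactly.
#'
#' @param masks named list of [structure_mask()]s on one grid.
#' @param path output file.
#' @param frame_of_reference_uid frame of reference UID shared with the dose.
#' @param patient_id patient/plan identifier.
#' @export
write_dicom_rtstruct <- function(masks, path,
                                 frame_of_reference_uid = dcm_uid("1.1"),
                                 patient_id = "kbdvh") {
  rois <- list(); rcs <- list()
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    rois[[k]] <- c(dcm_elem(0x3006, 0x0022, "IS", k),
                   dcm_elem(0x3006, 0x0024, "UI", frame_of_reference_uid),
                   dcm_elem(0x3006, 0x0026, "LO", m$name))
    cts <- mask_to_contours(m)
    items <- lapply(cts$contours, function(ct) {
      xyz <- rbind(t(ct$xy), ct$z)  # interleave x,y,z per vertex
      c(dcm_elem(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_elem(0x3006, 0x0046, "IS", nrow(ct$xy)),
        dcm_elem(0x3006, 0x0050, "DS", dcm_ds(as.numeric(xyz))))
    })
    rcs[[k]] <- c(dcm_elem(0x3006, 0x0040, "SQ", items),
                  dcm_elem(0x3006, 0x0084, "IS", k))
  }
  ds <- c(dcm_elem(0x0008, 0x0016, "UI", UID_RTSTRUCT),
          dcm_elem(0x0008, 0x0018, "UI", dcm_uid("2", as.integer(Sys.time()) %% 1e6)),
          dcm_elem(0x0008, 0x0060, "CS", "RTSTRUCT"),
          dcm_elem(0x0010, 0x0020, "LO", patient_id),
          dcm_elem(0x0020, 0x0052, "UI", frame_of_reference_uid),
          dcm_elem(0x3006, 0x0020, "SQ", rois),
          dcm_elem(0x3006, 0x0039, "SQ", rcs))
  dcm_file(UID_RTSTRUCT, dcm_uid("2.0"), ds, path)
}

#' Export a dose grid as a DICOM RT Dose file
#'
#' Dose is stored as uint16 pixel data with a DoseGridScaling factor
#' (quantization < 1e-3 Gy at 60 Gy), GRID/PHYSICAL type, axial frames.
#'
#' @param dose a [dose_grid()].
#' @param path output file.
#' @param frame_of_reference_uid frame of reference UID shared with the
#'   structure set.
#' @param patient_id patient/plan identifier.
#' @export
write_dicom_rtdose <- function(dose, path,
                               frame_of_reference_uid = dcm_uid("1.1"),
                               patient_id = "kbdvh") {
  g <- dose$grid
  maxd <- max(dose$dose)
  scaling <- if (maxd > 0) maxd / 65535 else 1
  px <- as.integer(round(dose$dose / scaling))  # x fastest = column fastest
  pdata <- writeBin(px, raw(), size = 2L, endian = "little")
  zoff <- (seq_len(g$shape[3]) - 1) * g$spacing[3]
  ds <- c(dcm_elem(0x0008, 0x0016, "UI", UID_RTDOSE),
          dcm_elem(0x0008, 0x0018, "UI", dcm_uid("3", as.integer(Sys.time()) %% 1e6)),
          dcm_elem(0x0008, 0x0060, "CS", "RTDOSE"),
          dcm_elem(0x0010, 0x0020, "LO", patient_id),
          dcm_elem(0x0020, 0x0032, "DS", dcm_ds(g$origin)),
          dcm_elem(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
          dcm_elem(0x0020, 0x0052, "UI", frame_of_reference_uid),
          dcm_elem(0x0028, 0x0002, "US", 1L),
          dcm_elem(0x0028, 0x0008, "IS", g$shape[3]),
          dcm_elem(0x0028, 0x0010, "US", g$shape[2]),  # rows = y
          dcm_elem(0x0028, 0x0011, "US", g$shape[1]),  # columns = x
          dcm_elem(0x0028, 0x0030, "DS", dcm_ds(c(g$spacing[2], g$spacing[1]))),
          dcm_elem(0x0028, 0x0100, "US", 16L),
          dcm_elem(0x0028, 0x0101, "US", 16L),
          dcm_elem(0x0028, 0x0102, "US", 15L),
          dcm_elem(0x0028, 0x0103, "US", 0L),
          dcm_elem(0x3004, 0x0002, "CS", "GY"),
          dcm_elem(0x3004, 0x0004, "CS", "PHYSICAL"),
          dcm_elem(0x3004, 0x000A, "CS", "PLAN"),
          dcm_elem(0x3004, 0x000C, "DS", dcm_ds(zoff)),
          dcm_elem(0x3004, 0x000E, "DS", sprintf("%.15e", scaling)),
          dcm_elem(0x7FE0, 0x0010, "OW", pdata))
  dcm_file(UID_RTDOSE, dcm_uid("3.0"), ds, path)
}

# --- parsing ---------------------------------------------------------------

dcm_parse_dataset <- function(bytes, pos = 1L, end = length(bytes)) {
  out <- list()
  while (pos <= end - 7L) {
    grp <- readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    ele <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                     signed = FALSE, endian = "little")
      pos <- pos + 8L
    }
    if (len < 0)
      kb_stop("format_error", "undefined-length element not supported")
    val_raw <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04X%04X", grp, ele)
    out[[key]] <- dcm_decode(vr, val_raw)
  }
  out
}

dcm_decode <- function(vr, val) {
  val_str <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
  if (vr %in% c("UI", "SH", "CS", "LO", "PN", "DA", "TM", "ST")) {
    val_str(val)
  } else if (vr %in% c("DS", "IS")) {
    s <- val_str(val)
    if (nchar(s) == 0) numeric(0) else as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr == "US") {
    readBin(val, "integer", n = length(val) / 2, size = 2, signed = FALSE,
            endian = "little")
  } else if (vr == "UL") {
    readBin(val, "integer", n = length(val) / 4, size = 4, endian = "little")
  } else if (vr == "SQ") {
    items <- list()
    pos <- 1L
    while (pos <= length(val) - 7L) {
      tag <- readBin(val[pos:(pos + 3)], "integer", n = 2, size = 2,
                     signed = FALSE, endian = "little")
      ilen <- readBin(val[(pos + 4):(pos + 7)], "integer", size = 4,
                      endian = "little")
      pos <- pos + 8L
      if (!(tag[1] == 0xFFFE && tag[2] == 0xE000))
        kb_stop("format_error", "malformed sequence item tag")
      if (ilen < 0)
        kb_stop("format_error", "undefined-length sequence item not supported")
      items[[length(items) + 1]] <-
        dcm_parse_dataset(val, pos, pos + ilen - 1L)
      pos <- pos + ilen
    }
    items
  } else {
    val  # OW and friends stay raw
  }
}

dcm_read_file <- function(path) {
  if (!file.exists(path)) kb_stop("io_error", "DICOM file not found: %s", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    kb_stop("format_error", "not a DICOM part-10 file: %s", path)
  ds <- dcm_parse_dataset(bytes, 133L)
  ts <- ds[["00020010"]]
  if (!is.null(ts) && !identical(ts, UID_EXPLICIT_VR_LE))
    kb_stop("format_error", "unsupported transfer syntax '%s'", ts)
  ds
}

#' Read a DICOM RT Structure Set / RT Dose pair into a plan bundle
#'
#' Structures come back as [contour_set()]s (rasterize with
#' [rasterize_contours()] or let [prepare_plan()]-based workflows do it);
#' the dose grid has its scaling applied to Gy. A frame-of-reference mismatch
#' between the two files is an error unless explicitly overridden.
#'
#' @param structure_set_path RT Structure Set file.
#' @param dose_path RT Dose file.
#' @param plan_id identifier for the bundle (default: the file's PatientID).
#' @param ignore_frame_mismatch proceed on frame-of-reference mismatch
#'   (logged) instead of erroring.
#' @return A `plan_bundle` whose `structures` are [contour_set()]s.
#' @export
read_dicom_rt <- function(structure_set_path, dose_path, plan_id = NULL,
                          ignore_frame_mismatch = FALSE) {
  sds <- dcm_read_file(structure_set_path)
  if (!identical(sds[["00080060"]], "RTSTRUCT"))
    kb_stop("format_error", "expected RTSTRUCT, found modality '%s' in %s",
            sds[["00080060"]] %||% "<none>", structure_set_path)
  dds <- dcm_read_file(dose_path)
  if (!identical(dds[["00080060"]], "RTDOSE"))
    kb_stop("format_error", "expected RTDOSE, found modality '%s' in %s",
            dds[["00080060"]] %||% "<none>", dose_path)
  f1 <- sds[["00200052"]]; f2 <- dds[["00200052"]]
  if (!is.null(f1) && !is.null(f2) && !identical(f1, f2)) {
    if (!ignore_frame_mismatch)
      kb_stop("format_error", "frame-of-reference mismatch between %s and %s",
              structure_set_path, dose_path)
    kb_warn("frame_warning", "frame-of-reference mismatch; proceeding on override")
  }

  rois <- sds[["30060020"]]
  if (is.null(rois) || length(rois) == 0)
    kb_stop("empty_plan_error", "structure set has zero ROIs")
  roi_names <- stats::setNames(
    vapply(rois, function(r) r[["30060026"]], "a"),
    vapply(rois, function(r) as.character(r[["30060022"]]), "a"))
  structures <- list()
  for (rc in sds[["30060039"]]) {
    num <- as.character(rc[["30060084"]])
    nm <- roi_names[[num]]
    cts <- lapply(rc[["30060040"]] %||% list(), function(it) {
      xyz <- matrix(it[["30060050"]], nrow = 3)
      list(z = xyz[3, 1], xy = t(xyz[1:2, , drop = FALSE]))
    })
    structures[[nm]] <- contour_set(nm, cts)
  }

  scaling <- dds[["3004000E"]]
  if (is.null(scaling))
    kb_stop("format_error", "RT Dose lacks DoseGridScaling (3004,000E)")
  nx <- dds[["00280011"]]; ny <- dds[["00280010"]]
  nz <- if (!is.null(dds[["00280008"]])) as.integer(dds[["00280008"]]) else 1L
  ps <- dds[["00280030"]]  # row spacing (y), column spacing (x)
  zoff <- dds[["3004000C"]]
  dz <- if (length(zoff) > 1) diff(zoff[1:2]) else 1
  origin <- dds[["00200032"]]
  grid <- volume_grid(c(nx, ny, nz), c(ps[2], ps[1], dz), origin)
  px <- readBin(dds[["7FE00010"]], "integer", n = nx * ny * nz, size = 2,
                signed = FALSE, endian = "little")
  dose <- dose_grid(grid, array(px * scaling, dim = grid$shape))
  structure(list(plan_id = plan_id %||% sds[["00100020"]] %||% "dicom_plan",
                 structures = structures, dose = dose,
                 prescription_gy = NULL),
            class = "plan_bundle")
}

#' Reconstruct per-slice boundary contours from a binary mask
#'
#' Traces the rectilinear boundary of the union of occupied voxel footprints
#' on every slice: directed edges between occupied and empty voxels are
#' chained into closed loops (outer boundaries counter-clockwise, holes
#' clockwise), then collinear runs are merged. Voxel centers are strictly
#' inside or outside these polygons, so even-odd rasterization inverts the
#' construction exactly.
#'
#' @param mask a [structure_mask()].
#' @return A [contour_set()].
#' @export
mask_to_contours <- function(mask) {
  g <- mask$grid
  ax <- grid_axes(g)
  hx <- g$spacing[1] / 2; hy <- g$spacing[2] / 2
  contours <- list()
  for (k in seq_len(g$shape[3])) {
    occ <- mask$occupancy[, , k, drop = TRUE]
    if (!any(occ)) next
    occ <- matrix(occ, nrow = g$shape[1])
    pad <- matrix(FALSE, nrow(occ) + 2, ncol(occ) + 2)
    pad[2:(nrow(occ) + 1), 2:(ncol(occ) + 1)] <- occ
    idx <- which(occ, arr.ind = TRUE)
    edges <- list()
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      cx <- ax$x[i]; cy <- ax$y[j]
      x0 <- cx - hx; x1 <- cx + hx; y0 <- cy - hy; y1 <- cy + hy
      if (!pad[i + 1, j])     edges[[length(edges) + 1]] <- c(x0, y0, x1, y0)  # bottom
      if (!pad[i + 2, j + 1]) edges[[length(edges) + 1]] <- c(x1, y0, x1, y1)  # right
      if (!pad[i + 1, j + 2]) edges[[length(edges) + 1]] <- c(x1, y1, x0, y1)  # top
      if (!pad[i, j + 1])     edges[[length(edges) + 1]] <- c(x0, y1, x0, y0)  # left
    }
    loops <- chain_edges(edges)
    for (lp in loops)
      contours[[length(contours) + 1]] <- list(z = ax$z[k], xy = lp)
  }
  contour_set(mask$name, contours)
}

# Chain directed rectilinear edges into closed loops; merge collinear runs.
chain_edges <- function(edges) {
  if (length(edges) == 0) return(list())
  em <- do.call(rbind, edges)
  key <- function(x, y) sprintf("%.6f_%.6f", x, y)
  from <- key(em[, 1], em[, 2])
  used <- rep(FALSE, nrow(em))
  by_from <- split(seq_len(nrow(em)), from)
  loops <- list()
  for (start in seq_len(nrow(em))) {
    if (used[start]) next
    path <- start
    used[start] <- TRUE
    repeat {
      tip <- em[path[length(path)], 3:4]
      cand <- by_from[[key(tip[1], tip[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      path <- c(path, nxt)
    }
    pts <- em[path, 1:2, drop = FALSE]
    # merge collinear consecutive segments (closed polygon)
    n <- nrow(pts)
    keep <- vapply(seq_len(n), function(p) {
      prev <- pts[if (p == 1) n else p - 1, ]
      nxt <- pts[if (p == n) 1 else p + 1, ]
      v1 <- pts[p, ] - prev; v2 <- nxt - pts[p, ]
      abs(v1[1] * v2[2] - v1[2] * v2[1]) > 1e-9
    }, TRUE)
    loops[[length(loops) + 1]] <- pts[keep, , drop = FALSE]
  }
  loops
}
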