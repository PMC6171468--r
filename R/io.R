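# Format IO and validation: OBJ/PLY meshes with a sidecar manifest,
# granule/event CSV and JSONL, scene recipes, and run manifests.  All readers
# validate and reject malformed input with located errors; none silently
# coerces.  Conventions (stated once, enforced here): coordinates are
# 0-based um in a right-handed frame; voxel cells are half-open; PLY binary
# little-endian is the canonical mesh interchange, OBJ is accepted for
# convenience.

#' Write / read a mesh as Wavefront OBJ (ASCII)
#'
#' @param m a `surface_mesh`.
#' @param path file path.
#' @param class,id class label and object id to attach on read (OBJ itself
#'   carries neither; they normally come from the scene manifest).
#' @return `read_obj()` returns a validated `surface_mesh`.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# surface_mesh id ", m$id, " class ", m$class),
    paste("v", format(m$vertices[, 1], digits = 17, trim = TRUE),
          format(m$vertices[, 2], digits = 17, trim = TRUE),
          format(m$vertices[, 3], digits = 17, trim = TRUE)),
    paste("f", m$faces[, 1], m$faces[, 2], m$faces[, 3])
  ), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path, class = "axon", id = 1L) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop(path, ": no vertices or no faces")
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[2:4]))
    if (any(is.na(v))) stop(path, ": malformed vertex line '",
                            paste(x, collapse = " "), "'")
    v
  }))
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    # tolerate v/vt/vn references; use the vertex index
    f <- suppressWarnings(as.integer(sub("/.*$", "", x[2:4])))
    if (any(is.na(f))) stop(path, ": malformed face line '",
                            paste(x, collapse = " "), "'")
    f
  }))
  surface_mesh(V, F, class = class, id = id)
}

#' Write / read a mesh as PLY
#'
#' Binary little-endian PLY is the canonical interchange (exact float64
#' round trip); ASCII PLY is also written/read on request.  An optional
#' per-vertex scalar (e.g. an absorption map) is stored as a `quality`
#' property.
#'
#' @param m a `surface_mesh`.
#' @param path file path.
#' @param binary write binary little-endian (default) or ASCII.
#' @param scalar optional per-vertex numeric attribute.
#' @param class,id attached on read (from the scene manifest).
#' @return `read_ply()` returns a validated `surface_mesh`; if the file has
#'   a `quality` property it is attached as attribute `scalar`.
#' @export
write_ply <- function(m, path, binary = TRUE, scalar = NULL) {
  nv <- nrow(m$vertices)
  nf <- nrow(m$faces)
  if (!is.null(scalar) && length(scalar) != nv)
    stop("scalar must have one value per vertex")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ply",
    paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
    paste0("comment surface_mesh id ", m$id, " class ", m$class),
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    if (!is.null(scalar)) "property double quality",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header")
  writeLines(hdr, con)
  vdat <- if (is.null(scalar)) t(m$vertices) else t(cbind(m$vertices, scalar))
  if (binary) {
    writeBin(as.vector(vdat), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(vdat, 2, function(r)
      paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
    writeLines(paste(3L, m$faces[, 1] - 1L, m$faces[, 2] - 1L,
                     m$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path, class = "axon", id = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop(path, ": truncated PLY header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (hdr[1] != "ply") stop(path, ": not a PLY file")
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  binary <- startsWith(fmt, "binary_little_endian")
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1]))
  vprops <- sub("^property double ", "",
                grep("^property double ", hdr, value = TRUE))
  np <- length(vprops)
  has_scalar <- "quality" %in% vprops
  if (binary) {
    vdat <- matrix(readBin(con, "double", nv * np, size = 8,
                           endian = "little"), ncol = np, byrow = TRUE)
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop(path, ": non-triangular face at face ", i)
      F[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else {
    rest <- readLines(con)
    vdat <- do.call(rbind, lapply(strsplit(rest[seq_len(nv)], "\\s+"),
                                  function(x) as.numeric(x[seq_len(np)])))
    F <- do.call(rbind, lapply(strsplit(rest[nv + seq_len(nf)], "\\s+"),
                               function(x) {
      if (as.integer(x[1]) != 3L) stop(path, ": non-triangular face")
      as.integer(x[2:4]) + 1L
    }))
  }
  m <- surface_mesh(vdat[, 1:3, drop = FALSE], F, class = class, id = id)
  if (has_scalar) attr(m, "scalar") <- vdat[, which(vprops == "quality")]
  m
}

#' Read a mesh (OBJ or PLY) with manifest metadata
#'
#' @param path mesh file (`.obj` or `.ply`).
#' @param manifest_row optional list/row with `class` and `id`.
#' @return a validated `surface_mesh`.
#' @export
read_mesh <- function(path, manifest_row = NULL) {
  cls <- if (is.null(manifest_row)) "axon" else as.character(manifest_row$class)
  id <- if (is.null(manifest_row)) 1L else as.integer(manifest_row$id)
  if (!cls %in% MESH_CLASSES)
    stop("manifest class '", cls, "' outside the allowed label set")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path, class = cls, id = id),
         ply = read_ply(path, class = cls, id = id),
         stop("unsupported mesh format: .", ext))
}

#' Write / load a whole scene (meshes + manifest CSV)
#'
#' `write_scene()` writes one OBJ per mesh plus `manifest.csv` (path, class,
#' id); `read_scene()` loads and validates them all.
#'
#' @param meshes list of `surface_mesh`.
#' @param dir scene directory.
#' @return `read_scene()` returns the mesh list.
#' @export
write_scene <- function(meshes, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create scene directory ", dir)
  rows <- lapply(meshes, function(m) {
    fn <- sprintf("mesh_%03d.obj", m$id)
    write_obj(m, file.path(dir, fn))
    data.frame(path = fn, class = m$class, id = m$id)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  need <- c("path", "class", "id")
  if (!all(need %in% names(man)))
    stop(mf, ": manifest must have columns ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(man)), function(i)
    read_mesh(file.path(dir, man$path[i]), man[i, ]))
}

validate_granules <- function(g) {
  need <- c("x", "y", "z", "r")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop("granule table missing column(s): ", paste(missing, collapse = ", "))
  for (col in need) {
    bad <- which(!is.finite(g[[col]]))
    if (length(bad))
      stop("granule table: non-finite ", col, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(g$r <= 0)
  if (length(bad))
    stop("granule table: non-positive radius at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(g)
}

validate_events <- function(ev) {
  need <- c("t", "x", "y", "z", "q")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    stop("event table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(ev)) {
    fin <- is.finite(as.matrix(ev[need]))
    bad <- which(rowSums(fin) < length(need))
    if (length(bad))
      stop("event table: non-finite value at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    bad <- which(ev$q <= 0)
    if (length(bad))
      stop("event table: non-positive quanta q at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (is.unsorted(ev$t))
      stop("event table: times not non-decreasing (first violation at row ",
           which(diff(ev$t) < 0)[1] + 1L, ")")
  }
  invisible(ev)
}

#' Read granule and event tables
#'
#' Granules: CSV with header `x,y,z,r[,host_id]`.  Events: CSV with header
#' `t,x,y,z,q`, or JSONL with one `{"t":..,"x":..,"y":..,"z":..,"q":..}`
#' object per line.  Both are schema-validated with row-numbered errors.
#'
#' @param path input file.
#' @return validated data.frame.
#' @export
read_granules <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_granules(g)
  if (is.null(g$host_id)) g$host_id <- 0L
  g
}

#' @rdname read_granules
#' @export
read_events <- function(path) {
  ext <- tolower(tools::file_ext(path))
  ev <- if (ext == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    do.call(rbind, lapply(seq_along(lines), function(i) {
      row <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e)
                        stop(path, ": line ", i, ": malformed JSON"))
      as.data.frame(row[c("t", "x", "y", "z", "q")])
    }))
  } else utils::read.csv(path, stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

#' Write events as CSV or JSONL
#' @param ev validated event data.frame.
#' @param path output path (`.csv` or `.jsonl`).
#' @export
write_events <- function(ev, path) {
  validate_events(ev)
  if (tolower(tools::file_ext(path)) == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(ev)))
      writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
  } else {
    utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Run manifest for exact replay
#'
#' Captures the configuration snapshot, parameter hash, seeds, package
#' version and input-file digests of a run; written as JSON next to the
#' outputs.  For deterministic modes this is sufficient to re-execute the
#' run bit-identically.
#'
#' @param config named list (configuration snapshot).
#' @param seeds named list of seeds used.
#' @param inputs character vector of input file paths (md5-digested).
#' @param extra further metadata to embed.
#' @return manifest list (class `run_manifest`).
#' @export
run_manifest <- function(config = list(), seeds = list(), inputs = character(0),
                         extra = list()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.list(unname(d)), basename(names(d)))
  } else list()
  structure(c(list(
    tool = "gliaflux",
    version = as.character(utils::packageVersion("gliaflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = seeds, input_digests = digests), extra),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
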