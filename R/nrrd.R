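# Minimal NRRD volume IO (ASCII encoding) and snapshot export.  Only the
# header fields this package writes are understood; that is sufficient for a
# lossless write -> read round trip of per-snapshot scalar volumes.

#' Write a 3D (or 4D) array as an ASCII NRRD file
#'
#' @param a numeric array (3D scalar volume, or 4D with time as the slowest
#'   axis).
#' @param path output path.
#' @param h voxel edge (um), written as diagonal space directions.
#' @param origin world origin (um triple).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(a, path, h = 1, origin = c(0, 0, 0)) {
  nd <- length(dim(a))
  if (!nd %in% c(3L, 4L)) stop("write_nrrd: array must be 3D or 4D")
  con <- file(path, "w")
  on.exit(close(con))
  dirs <- apply(diag(3) * h, 1, function(r)
    paste0("(", paste(format(r, trim = TRUE), collapse = ","), ")"))
  if (nd == 4L) dirs <- c(dirs, "none")
  writeLines(c(
    "NRRD0004",
    "type: double",
    paste("dimension:", nd),
    paste("sizes:", paste(dim(a), collapse = " ")),
    "space dimension: 3",
    paste("space directions:", paste(dirs, collapse = " ")),
    paste0("space origin: (", paste(format(origin, trim = TRUE),
                                    collapse = ","), ")"),
    "encoding: ascii",
    ""
  ), con)
  writeLines(paste(format(as.vector(a), digits = 17, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' Read an ASCII NRRD file written by [write_nrrd()]
#'
#' @param path file path.
#' @return numeric array with attributes `h` (voxel edge) and `origin`.
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "NRRD")) stop(path, ": not an NRRD file")
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop(path, ": missing header/data separator")
  header <- lines[2:(blank - 1)]
  field <- function(nm) {
    hit <- grep(paste0("^", nm, ": "), header, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", nm, ": "), "", hit[1])
  }
  if (!identical(field("encoding"), "ascii"))
    stop(path, ": only ascii encoding supported")
  sizes <- as.integer(strsplit(field("sizes"), " ")[[1]])
  vals <- as.numeric(strsplit(paste(lines[(blank + 1):length(lines)],
                                    collapse = " "), "\\s+")[[1]])
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(sizes))
    stop(path, ": expected ", prod(sizes), " values, got ", length(vals))
  a <- array(vals, dim = sizes)
  dirs <- field("space directions")
  if (!is.null(dirs)) {
    first <- regmatches(dirs, regexpr("\\(([^)]*)\\)", dirs))
    nums <- as.numeric(strsplit(gsub("[()]", "", first), ",")[[1]])
    attr(a, "h") <- max(abs(nums))
  }
  org <- field("space origin")
  if (!is.null(org))
    attr(a, "origin") <- as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]])
  a
}

#' Export a volumetric series as NRRD snapshots plus JSON metadata
#'
#' Writes one NRRD per species per snapshot
#' (`<species>_t<index>.nrrd`, index zero-padded), or a single 4D NRRD per
#' species with `per_snapshot = FALSE`, plus a `series.json` sidecar holding
#' species, snapshot times, normalization mode and the parameter hash when
#' supplied.
#'
#' @param series a `volumetric_series` from [simulate_grid()].
#' @param dir output directory (created if absent).
#' @param per_snapshot one file per snapshot (default) or one 4D file.
#' @param params optional parameters to hash into the sidecar.
#' @return character vector of written NRRD paths, invisibly.
#' @export
export_snapshots <- function(series, dir, per_snapshot = TRUE, params = NULL) {
  if (!inherits(series, "volumetric_series")) stop("not a volumetric_series")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  g <- series$grid
  paths <- character(0)
  for (s in series$species) {
    v <- series$values[[s]]
    if (per_snapshot) {
      wid <- max(4, nchar(nrow(v) - 1))
      for (i in seq_len(nrow(v))) {
        a <- array(v[i, ], dim = g$dims)
        p <- file.path(dir, sprintf("%s_t%0*d.nrrd", s, wid, i - 1L))
        write_nrrd(a, p, h = g$h, origin = g$origin)
        paths <- c(paths, p)
      }
    } else {
      a <- array(t(v), dim = c(g$dims, nrow(v)))
      p <- file.path(dir, paste0(s, "_4d.nrrd"))
      write_nrrd(a, p, h = g$h, origin = g$origin)
      paths <- c(paths, p)
    }
  }
  meta <- list(species = series$species, times = series$times,
               dims = g$dims, h = g$h, origin = g$origin,
               normalization = series$normalization,
               per_snapshot = per_snapshot)
  if (!is.null(params)) meta$params_hash <- params_hash(params)
  jsonlite::write_json(meta, file.path(dir, "series.json"), digits = NA)
  invisible(paths)
}
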