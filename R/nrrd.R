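#' Write a 3-d array as an NRRD volume
#'
#' Minimal NRRD0004 writer for the volumes this package produces: a single
#' attached-data file, `raw` (little-endian) or `ascii` encoding, with voxel
#' size and origin recorded as `space directions` / `space origin`.
#'
#' @param x 3-d numeric or logical array.
#' @param path output file path.
#' @param type `"double"` or `"uint8"`.
#' @param encoding `"raw"` or `"ascii"`.
#' @param voxel_size,origin grid geometry (mm).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, type = c("double", "uint8"),
                       encoding = c("raw", "ascii"),
                       voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  dm <- dim(x)
  if (length(dm) != 3)
    stop_letplan("write_nrrd expects a 3-d array", class = "letplan_io_error")
  vs <- rep(voxel_size, length.out = 3)
  hdr <- c(
    "NRRD0004",
    "# letplan volume",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dm, collapse = " ")),
    paste0("encoding: ", encoding),
    "endian: little",
    "space: left-posterior-superior",
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            vs[1], vs[2], vs[3]),
    sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3])
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  vals <- as.vector(x)
  if (type == "uint8") {
    if (encoding == "raw") writeBin(as.raw(as.integer(vals)), con)
    else writeLines(paste(as.integer(vals), collapse = " "), con)
  } else {
    if (encoding == "raw")
      writeBin(as.double(vals), con, size = 8, endian = "little")
    else writeLines(paste(format(vals, digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' Read an NRRD volume written by [write_nrrd()]
#'
#' @param path NRRD file path.
#' @return list with `data` (3-d array), `voxel_size`, `origin`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (length(magic) == 0 || !startsWith(magic, "NRRD"))
    stop_letplan("NRRD parse error: missing NRRD magic in '", path, "'",
                 class = "letplan_parse_error")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop_letplan("NRRD parse error: truncated header (no blank line) in '",
                   path, "'", class = "letplan_parse_error")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  for (need in c("type", "sizes", "encoding"))
    if (is.null(fields[[need]]))
      stop_letplan("NRRD parse error: missing field '", need, "'",
                   class = "letplan_parse_error")
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  n <- prod(sizes)
  type <- fields$type
  enc <- fields$encoding
  if (enc == "raw") {
    vals <- if (type == "uint8") as.numeric(readBin(con, "raw", n = n))
            else readBin(con, "double", n = n, size = 8, endian = "little")
  } else if (enc == "ascii") {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[!is.na(vals)]
  } else {
    stop_letplan("NRRD parse error: unsupported encoding '", enc, "'",
                 class = "letplan_parse_error")
  }
  if (length(vals) < n)
    stop_letplan("NRRD parse error: data shorter than sizes field",
                 class = "letplan_parse_error")
  vs <- c(1, 1, 1); org <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    m <- gregexpr("-?[0-9.eE+]+", fields[["space directions"]])
    nums <- as.numeric(regmatches(fields[["space directions"]], m)[[1]])
    vs <- c(nums[1], nums[5], nums[9])
  }
  if (!is.null(fields[["space origin"]])) {
    m <- gregexpr("-?[0-9.eE+]+", fields[["space origin"]])
    org <- as.numeric(regmatches(fields[["space origin"]], m)[[1]])
  }
  list(data = array(vals[seq_len(n)], dim = sizes), voxel_size = vs,
       origin = org)
}

#' Persist / restore a phantom as NRRD volumes plus a JSON sidecar
#'
#' `write_phantom()` stores the density grid as `density.nrrd`, each
#' structure mask as `mask_<name>.nrrd` (uint8), and the generating spec as
#' `spec.json`. `read_phantom()` restores an identical `phantom_grid`
#' (bitwise on density and masks).
#'
#' @param grid a `phantom_grid` from [build_phantom()].
#' @param dir directory to write into (created if needed).
#' @return `write_phantom()` returns `dir` invisibly; `read_phantom()`
#'   returns the `phantom_grid`.
#' @export
write_phantom <- function(grid, dir) {
  if (!inherits(grid, "phantom_grid"))
    stop_letplan("grid must be a phantom_grid", class = "letplan_io_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nrrd(grid$density, file.path(dir, "density.nrrd"), type = "double",
             voxel_size = grid$voxel_size, origin = grid$origin)
  for (nm in names(grid$masks))
    write_nrrd(grid$masks[[nm]], file.path(dir, paste0("mask_", nm, ".nrrd")),
               type = "uint8", voxel_size = grid$voxel_size,
               origin = grid$origin)
  spec <- grid$spec
  side <- list(
    archetype = spec$archetype, grid_shape = spec$grid_shape,
    voxel_size = spec$voxel_size, origin = spec$origin,
    target_ctv_volume = spec$target_ctv_volume,
    densities = spec$densities, geometry = spec$geometry,
    masks = names(grid$masks), achieved = grid$achieved
  )
  jsonlite::write_json(side, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  spec_path <- file.path(dir, "spec.json")
  if (!file.exists(spec_path))
    stop_letplan("phantom read error: missing spec.json in '", dir, "'",
                 class = "letplan_parse_error")
  side <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
  for (need in c("archetype", "grid_shape", "voxel_size", "origin"))
    if (is.null(side[[need]]))
      stop_letplan("phantom spec validation error: missing key '", need, "'",
                   class = "letplan_parse_error")
  spec <- phantom_spec(
    archetype = side$archetype, grid_shape = side$grid_shape,
    voxel_size = side$voxel_size, origin = side$origin,
    target_ctv_volume = side$target_ctv_volume,
    densities = as.list(side$densities),
    geometry = lapply(side$geometry, unlist)
  )
  den <- read_nrrd(file.path(dir, "density.nrrd"))
  masks <- lapply(setNames(nm = side$masks), function(nm) {
    vol <- read_nrrd(file.path(dir, paste0("mask_", nm, ".nrrd")))
    array(vol$data > 0, dim = dim(vol$data))
  })
  achieved <- side$achieved
  achieved$voxel_counts <- unlist(achieved$voxel_counts)
  structure(
    list(density = den$data, masks = masks, origin = den$origin,
         voxel_size = den$voxel_size, spec = spec, achieved = achieved),
    class = "phantom_grid"
  )
}
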