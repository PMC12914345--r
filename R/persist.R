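#' Persist / restore influence matrices
#'
#' Writes the sparse dose and LET matrices in MatrixMarket coordinate
#' format (`D.mtx`, `L.mtx`), the spot table as CSV, and a JSON manifest
#' carrying the matrix shape and the scenario.
#'
#' @param influence an `influence` object.
#' @param dir directory to write into (created if needed).
#' @return `write_influence()` returns `dir` invisibly; `read_influence()`
#'   returns the `influence`.
#' @export
write_influence <- function(influence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(influence$D, file.path(dir, "D.mtx"))
  Matrix::writeMM(influence$L, file.path(dir, "L.mtx"))
  spots <- as.data.frame(influence$spots)
  write.csv(spots, file.path(dir, "spots.csv"), row.names = FALSE)
  s <- influence$scenario
  jsonlite::write_json(
    list(shape = dim(influence$D),
         scenario = list(kind = s$kind, shift = s$shift,
                         range_scale = s$range_scale, id = s$id)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_influence
#' @export
read_influence <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop_letplan("influence read error: missing manifest.json in '", dir,
                 "'", class = "letplan_parse_error")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  D <- methods::as(Matrix::readMM(file.path(dir, "D.mtx")), "CsparseMatrix")
  L <- methods::as(Matrix::readMM(file.path(dir, "L.mtx")), "CsparseMatrix")
  if (!identical(dim(D), as.integer(man$shape)))
    stop_letplan("influence read error: matrix shape does not match ",
                 "manifest", class = "letplan_parse_error")
  spots <- utils::read.csv(file.path(dir, "spots.csv"))
  sc <- scenario(man$scenario$kind, shift = man$scenario$shift,
                 range_scale = man$scenario$range_scale,
                 id = man$scenario$id)
  structure(list(D = D, L = L, scenario = sc, spots = spots),
            class = "influence")
}

#' Persist / restore a scenario set as JSON
#'
#' @param scenarios a `scenario_set`.
#' @param path JSON file path.
#' @return `write_scenarios()` returns `path` invisibly;
#'   `read_scenarios()` returns the `scenario_set`.
#' @export
write_scenarios <- function(scenarios, path) {
  jsonlite::write_json(
    list(setup_mm = attr(scenarios, "setup_mm"),
         range_fraction = attr(scenarios, "range_fraction"),
         scenarios = lapply(scenarios, function(s)
           list(kind = s$kind, shift = s$shift,
                range_scale = s$range_scale, id = s$id))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  sc <- lapply(raw$scenarios, function(s)
    scenario(s$kind, shift = unlist(s$shift), range_scale = s$range_scale,
             id = s$id))
  structure(sc, setup_mm = raw$setup_mm,
            range_fraction = raw$range_fraction, class = "scenario_set")
}
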