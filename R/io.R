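# Column aliases for common upstream exports (ImageJ "Results" tables,
# Neurolucida exports). Keys are lower-cased before lookup; the dictionary
# can be extended per call via the `aliases` argument.
default_aliases <- c(
  "label" = "id", "name" = "id", "roi" = "id",
  "type" = "structure_type", "structure" = "structure_type",
  "area" = "area",
  "perim." = "perimeter", "perim" = "perimeter", "perimeter" = "perimeter",
  "minferet" = "feret_min", "min feret" = "feret_min",
  "feret_min" = "feret_min",
  "feret" = "feret_max", "maxferet" = "feret_max", "max feret" = "feret_max",
  "feret_max" = "feret_max",
  "x" = "centroid_x", "xm" = "centroid_x", "centroid_x" = "centroid_x",
  "y" = "centroid_y", "ym" = "centroid_y", "centroid_y" = "centroid_y"
)

#' Read a per-contour measurement table
#'
#' Reads a delimited-text table of per-structure measurements (one row per
#' segmented contour) as produced by upstream segmentation tools or by
#' [write_measurements()]. Expected canonical columns are `id`,
#' `structure_type`, `area` (um^2), `perimeter` (um), `feret_min`,
#' `feret_max`, `centroid_x`, `centroid_y` (um); common upstream spellings
#' (e.g. `MinFeret`, `Perim.`, `XM`/`YM`) are mapped through an alias
#' dictionary. Rows with non-numeric required fields are dropped and
#' reported with their line numbers. All lengths are micrometres by
#' convention.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param aliases Named character vector of extra `upstream -> canonical`
#'   column aliases, merged over the built-in dictionary.
#' @param required Canonical columns that must be present.
#' @return A data frame with canonical column names; the attribute
#'   `rejected` holds a data frame of dropped rows (`line`, `reason`).
#' @export
read_measurements <- function(path, sep = ",", aliases = NULL,
                              required = c("area", "perimeter")) {
  if (!file.exists(path))
    stop(sprintf("file '%s' not found", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  dict <- default_aliases
  if (!is.null(aliases)) dict[tolower(names(aliases))] <- aliases
  nm <- names(raw)
  hit <- match(tolower(nm), names(dict))
  nm[!is.na(hit)] <- dict[hit[!is.na(hit)]]
  names(raw) <- nm
  missing <- setdiff(required, nm)
  if (length(missing))
    stop(sprintf("required column(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  # ids and labels stay character; everything else is numeric when every
  # non-empty entry parses (required numeric columns are always coerced, so
  # malformed rows can be detected and dropped)
  text_cols <- c("id", "structure_type", "fiber_id", "axon_id", "reason",
                 "class", "quantity", "method", "valid", "component",
                 "sae_feasible")
  parsed <- raw
  num_cols <- character()
  for (cl in setdiff(nm, text_cols)) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    empty <- is.na(raw[[cl]]) | raw[[cl]] %in% c("", "NA", "NaN")
    if (cl %in% required || all(is.na(v) == empty)) {
      parsed[[cl]] <- v
      num_cols <- c(num_cols, cl)
    }
  }
  need_num <- intersect(setdiff(required, text_cols), num_cols)
  bad <- rep(FALSE, nrow(parsed))
  for (cl in need_num) bad <- bad | !is.finite(parsed[[cl]])
  rejected <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                         reason = rep("non-numeric required field",
                                      sum(bad)),
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    message(sprintf("read_measurements: rejected %d malformed row(s) at line(s) %s",
                    nrow(rejected),
                    paste(rejected$line, collapse = ", ")))
  out <- parsed[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (!"id" %in% names(out)) out$id <- as.character(seq_len(nrow(out)))
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_measurements
#' @param table Data frame to write.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write polygon contours (JSON-lines)
#'
#' One JSON object per line, `{"id": ..., "type": ..., "x": [...],
#' "y": [...]}`, coordinates in um (apply `um_per_pixel` for pixel data).
#' Self-intersecting polygons are read with a warning and flagged via the
#' attribute `flagged`; an empty file yields an empty list.
#'
#' @param path File path.
#' @param um_per_pixel Optional scale applied on read.
#' @param check_simple Test each polygon for self-intersection (quadratic
#'   in vertex count; off by default for large contours).
#' @return A named list of [contour()]s.
#' @export
read_contours <- function(path, um_per_pixel = NULL, check_simple = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file '%s' not found", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  flagged <- character()
  for (k in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[k]])
    ct <- contour(rec$x, rec$y, id = rec$id,
                  structure_type = rec$type)
    if (!is.null(um_per_pixel)) ct <- scale_contour(ct, um_per_pixel)
    if (check_simple && !is_simple_polygon(ct$x, ct$y)) {
      warning(sprintf("contour '%s' is self-intersecting", ct$id),
              call. = FALSE)
      flagged <- c(flagged, ct$id)
    }
    out[[ct$id]] <- ct
  }
  attr(out, "flagged") <- flagged
  out
}

#' @rdname read_contours
#' @param contours A [contour()] or list of contours.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour")) contours <- list(contours)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (ct in contours) {
    writeLines(jsonlite::toJSON(
      list(id = ct$id, type = ct$structure_type, x = ct$x, y = ct$y),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

# O(n^2) segment-intersection test; adjacent edges share endpoints and are
# excluded.
is_simple_polygon <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  seg_int <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy)
      (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(x[i], y[i], xn[i], yn[i], x[j], y[j])
    d2 <- d(x[i], y[i], xn[i], yn[i], xn[j], yn[j])
    d3 <- d(x[j], y[j], xn[j], yn[j], x[i], y[i])
    d4 <- d(x[j], y[j], xn[j], yn[j], xn[i], yn[i])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) if (seg_int(i, j)) return(FALSE)
  }
  TRUE
}

#' Append SAE columns to a measurement table
#'
#' Runs [solve_sae()] on the `area` and `perimeter` columns and appends
#' `sae_diameter`, `tilt_angle`, `rho`, `sae_feasible` (plus the three
#' traditional diameters `d_feret_min`, `d_area_circle`,
#' `d_perimeter_circle` for convenience).
#'
#' @param table Data frame with `area` and `perimeter` columns.
#' @param ... Passed to [solve_sae()].
#' @return The table with derived columns appended.
#' @export
add_sae_columns <- function(table, ...) {
  if (!all(c("area", "perimeter") %in% names(table)))
    stop("`table` needs `area` and `perimeter` columns", call. = FALSE)
  s <- solve_sae(table$area, table$perimeter, ...)
  table$sae_diameter <- s$minor_diameter
  table$tilt_angle <- s$tilt_angle
  table$rho <- s$rho
  table$sae_feasible <- s$feasible
  if ("feret_min" %in% names(table)) table$d_feret_min <- table$feret_min
  table$d_area_circle <- circle_diameter_from_area(table$area)
  table$d_perimeter_circle <- circle_diameter_from_perimeter(table$perimeter)
  table
}

#' Run configuration
#'
#' A serializable bundle of the tunable parameters of a run, written next
#' to every CLI output so results are reproducible from (inputs, config,
#' seed) alone.
#'
#' @param um_per_pixel Scale for pixel-space contours (NULL = already um).
#' @param n_terms Perimeter series terms for the SAE solve.
#' @param tolerance,max_iter Newton controls for [solve_sae()].
#' @param max_distance,require_containment Pairing filters
#'   ([pair_and_score()]).
#' @param bin_width Histogram bin width (um).
#' @param seed Integer seed.
#' @param verbose Logical.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(um_per_pixel = NULL, n_terms = 4L,
                       tolerance = 1e-10, max_iter = 100L,
                       max_distance = NULL, require_containment = FALSE,
                       bin_width = 0.5, seed = 1L, verbose = FALSE) {
  num_ok <- function(v) is.null(v) ||
    (is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0)
  for (nm in c("um_per_pixel", "tolerance", "max_iter", "max_distance",
               "bin_width"))
    if (!num_ok(get(nm)))
      stop(sprintf("`%s` must be a positive number or NULL", nm),
           call. = FALSE)
  structure(list(um_per_pixel = um_per_pixel, n_terms = as.integer(n_terms),
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 max_distance = max_distance,
                 require_containment = isTRUE(require_containment),
                 bin_width = bin_width, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  vals <- jsonlite::fromJSON(path)
  do.call(run_config, vals)
}
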