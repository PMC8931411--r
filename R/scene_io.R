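#' Construct a scene stack
#'
#' A `scene_stack` holds one year's multi-date, multi-band pixel grid: a 4-D
#' reflectance array `[row, col, date, band]`, a per-date validity mask, the
#' observation DOYs and a simple affine georeference. Invalid observations are
#' stored as `NaN` and must never be read by downstream stages.
#'
#' @param year year label.
#' @param dates integer DOYs (sorted on construction).
#' @param bands numeric array `[rows, cols, n_dates, n_bands]`.
#' @param valid logical array `[rows, cols, n_dates]`.
#' @param band_names ordered band names (default blue, green, red, nir).
#' @param transform list `x0, y0, pixel_size` (upper-left corner, meters).
#' @return a `scene_stack`.
#' @export
new_scene_stack <- function(year, dates, bands, valid,
                            band_names = c("blue", "green", "red", "nir"),
                            transform = list(x0 = 0, y0 = 0, pixel_size = 16)) {
  stopifnot(length(dim(bands)) == 4, length(dim(valid)) == 3,
            all(dim(bands)[1:3] == dim(valid)),
            dim(bands)[4] == length(band_names),
            length(dates) == dim(bands)[3])
  ord <- order(dates)
  if (any(diff(as.integer(dates)[ord]) == 0)) stop("duplicate DOYs in stack")
  structure(list(year = as.character(year), dates = as.integer(dates)[ord],
                 bands = bands[, , ord, , drop = FALSE],
                 valid = valid[, , ord, drop = FALSE],
                 band_names = band_names, transform = transform),
            class = "scene_stack")
}

#' @export
dim.scene_stack <- function(x) dim(x$valid)

#' Write / read a scene stack as plain-text grids
#'
#' One whitespace-delimited numeric matrix per date and band
#' (`doy<DOY>_<band>.txt`), one 0/1 mask per date (`doy<DOY>_mask.txt`), and a
#' JSON sidecar `scene.json` with year, DOY list, band names, nodata value and
#' georeference. Invalid cells are written as the nodata value; on read they
#' come back as `NaN` with a `FALSE` mask. Dates are sorted on read whatever
#' their order in the sidecar.
#'
#' @param stack a `scene_stack`.
#' @param dir_path directory to write into (created if needed).
#' @return `write_scene` the directory, invisibly; `read_scene` a
#'   `scene_stack`.
#' @export
write_scene <- function(stack, dir_path) {
  stopifnot(inherits(stack, "scene_stack"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  nodata <- -9999
  side <- list(year = stack$year, doys = stack$dates,
               band_names = stack$band_names, nodata = nodata,
               nrow = dim(stack$bands)[1], ncol = dim(stack$bands)[2],
               transform = stack$transform)
  jsonlite::write_json(side, file.path(dir_path, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  for (d in seq_along(stack$dates)) {
    doy <- stack$dates[d]
    m <- stack$valid[, , d]
    for (k in seq_along(stack$band_names)) {
      g <- stack$bands[, , d, k]
      g[!m] <- nodata
      data.table::fwrite(data.table::as.data.table(g),
                         file.path(dir_path, sprintf("doy%03d_%s.txt", doy,
                                                     stack$band_names[k])),
                         sep = " ", col.names = FALSE)
    }
    data.table::fwrite(data.table::as.data.table(m * 1L),
                       file.path(dir_path, sprintf("doy%03d_mask.txt", doy)),
                       sep = " ", col.names = FALSE)
  }
  invisible(dir_path)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir_path) {
  side_path <- file.path(dir_path, "scene.json")
  if (!file.exists(side_path))
    stop("scene sidecar missing: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  doys <- as.integer(side$doys)
  bn <- as.character(side$band_names)
  nr <- side$nrow; nc <- side$ncol
  bands <- array(NA_real_, c(nr, nc, length(doys), length(bn)))
  valid <- array(TRUE, c(nr, nc, length(doys)))
  for (d in seq_along(doys)) {
    mf <- file.path(dir_path, sprintf("doy%03d_mask.txt", doys[d]))
    m <- as.matrix(data.table::fread(mf, header = FALSE)) == 1
    if (!all(dim(m) == c(nr, nc)))
      stop(sprintf("mask for DOY %d has shape %dx%d, expected %dx%d",
                   doys[d], nrow(m), ncol(m), nr, nc))
    valid[, , d] <- m
    for (k in seq_along(bn)) {
      f <- file.path(dir_path, sprintf("doy%03d_%s.txt", doys[d], bn[k]))
      g <- as.matrix(data.table::fread(f, header = FALSE))
      if (!all(dim(g) == c(nr, nc)))
        stop(sprintf("band %s DOY %d has shape %dx%d, expected %dx%d",
                     bn[k], doys[d], nrow(g), ncol(g), nr, nc))
      g[g == side$nodata] <- NaN
      valid[, , d] <- valid[, , d] & is.finite(g)
      bands[, , d, k] <- g
    }
    bands[, , d, ][!valid[, , d]] <- NaN
  }
  new_scene_stack(year = side$year, dates = doys, bands = bands, valid = valid,
                  band_names = bn,
                  transform = side$transform)
}

#' Radiometric calibration coefficients
#'
#' @param gain gain in W m-2 sr-1 um-1 per digital number; must be positive.
#' @param offset offset in W m-2 sr-1 um-1.
#' @return a `calibration_coefficients` list.
#' @export
calibration_coefficients <- function(gain, offset = 0) {
  if (!is.numeric(gain) || gain <= 0) stop("gain must be > 0")
  structure(list(gain = gain, offset = offset),
            class = "calibration_coefficients")
}

#' Convert digital numbers to at-sensor radiance
#'
#' `Le = Gain * DN + Offset`, elementwise; `NA`/`NaN` cells (masked
#' observations) stay masked.
#'
#' @param dn numeric vector/matrix/array of digital numbers.
#' @param coeffs a [calibration_coefficients()].
#' @return radiance in the same shape as `dn`.
#' @export
dn_to_radiance <- function(dn, coeffs) {
  stopifnot(inherits(coeffs, "calibration_coefficients"))
  coeffs$gain * dn + coeffs$offset
}

SAMPLE_COLS <- c("id", "year", "row", "col", "class", "provenance",
                 "similarity")

.validate_samples <- function(s, classes = NULL, grid_dim = NULL) {
  missing_cols <- setdiff(c("id", "year", "row", "col", "class"), names(s))
  if (length(missing_cols))
    stop("sample table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(classes)) {
    bad <- setdiff(unique(s$class), classes)
    if (length(bad))
      stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(grid_dim)) {
    out <- which(s$row < 0 | s$row >= grid_dim[1] |
                   s$col < 0 | s$col >= grid_dim[2])
    if (length(out))
      stop("sample(s) outside grid at index: ", paste(out, collapse = ", "))
  }
  if (is.null(s$provenance)) s$provenance <- "field"
  if (is.null(s$similarity)) s$similarity <- NA_real_
  data.table::setcolorder(data.table::as.data.table(s),
                          intersect(SAMPLE_COLS, names(s)))[]
}

#' Read / write labeled sample points
#'
#' CSV (columns `id, year, row, col, class, provenance, similarity`) or
#' GeoJSON points (same fields as properties; geometry at pixel centers).
#' Round-trips are lossless including provenance and similarity.
#'
#' @param path file path; format chosen by extension (`.csv` vs
#'   `.geojson`/`.json`).
#' @param classes optional allowed class labels; unknown labels error.
#' @param grid_dim optional `c(rows, cols)`; out-of-grid samples error.
#' @param samples a sample table.
#' @param transform affine georeference used for GeoJSON coordinates.
#' @return `read_samples` a `data.table`; `write_samples` the path invisibly.
#' @export
read_samples <- function(path, classes = NULL, grid_dim = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    rows <- lapply(gj$features, function(f) {
      p <- f$properties
      data.table::data.table(
        id = as.character(p$id), year = as.character(p$year),
        row = as.integer(p$row), col = as.integer(p$col),
        class = as.character(p$class),
        provenance = as.character(p$provenance %||% "field"),
        similarity = as.numeric(p$similarity %||% NA_real_))
    })
    s <- data.table::rbindlist(rows)
  } else {
    s <- data.table::fread(path,
                           colClasses = list(character = c("id", "year",
                                                           "class")))
  }
  .validate_samples(s, classes, grid_dim)
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path,
                          transform = list(x0 = 0, y0 = 0, pixel_size = 16)) {
  s <- .validate_samples(samples)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(s)), function(i) {
      x <- transform$x0 + (s$col[i] + 0.5) * transform$pixel_size
      y <- transform$y0 - (s$row[i] + 0.5) * transform$pixel_size
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(x, y)),
           properties = as.list(s[i, ]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    data.table::fwrite(s, path)
  }
  invisible(path)
}
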