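#' Scene simulation configuration
#'
#' Describes a synthetic multi-year agricultural scene: a rectangular pixel
#' grid tiled by rectangular fields, each field planted with one crop per year
#' (optionally rotated between years), observed on an irregular day-of-year
#' (DOY) grid with cloud-like gaps.
#'
#' Defaults mimic a 4-band (blue/green/red/NIR) 16 m wide-swath sensor
#' revisiting every 8 days over the main growing season (DOY 139-294).
#'
#' @param grid_rows,grid_cols pixel counts of the scene grid.
#' @param pixel_size_m nominal ground sampling distance in meters.
#' @param n_fields requested number of rectangular fields; rounded up to the
#'   nearest `r x c` tiling (see [generate_scene_series()]).
#' @param crop_classes ordered character vector of class names.
#' @param crop_proportions fractions (summing to 1) with which fields are
#'   assigned to classes.
#' @param rotation_rate fraction of fields changing crop between consecutive
#'   years, in `[0, 1]`.
#' @param years labels of the simulated years (order defines succession).
#' @param doy_grid candidate observation DOYs (strictly increasing).
#' @param missing_rate per-date, per-tile probability that an observation is
#'   invalid (cloud), in `[0, 1]`.
#' @param phase_shift_sd_days SD (days) of the per-year global phenology shift.
#' @param field_phase_sd_days SD (days) of the per-field sowing-date offset,
#'   drawn once per field (a field identity, constant across years).
#' @param field_amp_sd SD of the per-field multiplicative amplitude scale
#'   (management/soil variability), also constant across years.
#' @param noise_sd SD of additive Gaussian reflectance noise per band.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(grid_rows = 64, grid_cols = 64, pixel_size_m = 16,
                         n_fields = 100,
                         crop_classes = c("maize", "rice", "soybean", "other"),
                         crop_proportions = c(0.45, 0.2, 0.25, 0.1),
                         rotation_rate = 0,
                         years = c("2017", "2018"),
                         doy_grid = seq(139L, 294L, by = 8L),
                         missing_rate = 0.1,
                         phase_shift_sd_days = 10,
                         field_phase_sd_days = 3,
                         field_amp_sd = 0.05,
                         noise_sd = 0.02,
                         seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_fields >= 1,
            length(crop_classes) >= 2,
            length(crop_proportions) == length(crop_classes),
            length(years) >= 1)
  if (abs(sum(crop_proportions) - 1) > 1e-9)
    stop("crop_proportions must sum to 1")
  if (rotation_rate < 0 || rotation_rate > 1) stop("rotation_rate not in [0,1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate not in [0,1]")
  if (any(diff(doy_grid) <= 0)) stop("doy_grid must be strictly increasing")
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_size_m = pixel_size_m, n_fields = as.integer(n_fields),
    crop_classes = as.character(crop_classes),
    crop_proportions = crop_proportions, rotation_rate = rotation_rate,
    years = as.character(years), doy_grid = as.integer(doy_grid),
    missing_rate = missing_rate, phase_shift_sd_days = phase_shift_sd_days,
    field_phase_sd_days = field_phase_sd_days, field_amp_sd = field_amp_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "scene_config")
}

#' Crop phenology template
#'
#' A double-logistic seasonal NDVI curve, parameterized by the DOY of the
#' greenness peak, the seasonal amplitude above a bare/background baseline,
#' and the season width. Rice can carry an early-season paddy-flooding signal
#' (depressed NDVI, elevated NDWI before green-up).
#'
#' @param crop class name the template belongs to.
#' @param peak_doy DOY of maximum NDVI.
#' @param amplitude seasonal NDVI amplitude (`0 < amplitude <= 1`).
#' @param base_ndvi off-season NDVI baseline (`base_ndvi + amplitude <= 1`).
#' @param width_days distance in days between green-up and senescence
#'   midpoints.
#' @param early_water_signal logical; paddy flooding before green-up.
#' @return a `phenology_template` list.
#' @export
phenology_template <- function(crop, peak_doy, amplitude, base_ndvi,
                               width_days, early_water_signal = FALSE) {
  stopifnot(amplitude > 0, amplitude <= 1, base_ndvi + amplitude <= 1,
            width_days > 0)
  structure(list(crop = crop, peak_doy = peak_doy, amplitude = amplitude,
                 base_ndvi = base_ndvi, width_days = width_days,
                 early_water_signal = isTRUE(early_water_signal)),
            class = "phenology_template")
}

#' Default per-crop phenology templates
#'
#' Plausible northern-hemisphere summer-crop shapes with NDVI peaks inside
#' DOY 192-212; "other" is a broader, flatter curve standing in for
#' grass/forest/background vegetation.
#'
#' @param crop_classes class names to build templates for; unknown names get
#'   the generic "other" shape.
#' @return named list of [phenology_template()] objects.
#' @export
default_phenology_templates <- function(crop_classes = c("maize", "rice",
                                                         "soybean", "other")) {
  known <- list(
    maize   = phenology_template("maize",   205, 0.62, 0.16, 110),
    rice    = phenology_template("rice",    212, 0.58, 0.12, 100,
                                 early_water_signal = TRUE),
    soybean = phenology_template("soybean", 197, 0.55, 0.18,  95),
    other   = phenology_template("other",   192, 0.38, 0.24, 130)
  )
  out <- lapply(crop_classes, function(cl) {
    t <- known[[cl]] %||% known[["other"]]
    t$crop <- cl
    t
  })
  setNames(out, crop_classes)
}

# logistic rise used by both NDVI and the paddy-water signal
.rise <- function(doy, start, rate) 1 / (1 + exp(-(doy - start) / rate))

#' Evaluate a phenology template
#'
#' Double-logistic NDVI:
#' `base + amplitude * rise(doy - shift) * fall(doy - shift)`, with logistic
#' rise/fall midpoints at `peak_doy +/- width_days/2` and rate `width/12`
#' (so the value at `peak_doy` is within 1% of `base + amplitude`). For rice
#' templates, pre-green-up NDVI is additionally depressed by paddy flooding.
#'
#' @param template a [phenology_template()].
#' @param doy day-of-year vector.
#' @param phase_shift days the whole curve is shifted (positive = later).
#' @return NDVI values in `[-1, 1]`.
#' @export
phenology_value <- function(template, doy, phase_shift = 0) {
  t <- doy - phase_shift
  half <- template$width_days / 2
  rate <- template$width_days / 12
  rise <- .rise(t, template$peak_doy - half, rate)
  fall <- 1 - .rise(t, template$peak_doy + half, rate)
  v <- template$base_ndvi + template$amplitude * rise * fall
  if (template$early_water_signal) v <- v - 0.10 * (1 - rise)
  pmin(1, pmax(-1, v))
}

# Target NDWI (green/NIR form): broadly anti-correlated with NDVI; flooded
# paddies push it up before green-up.
.ndwi_value <- function(template, doy, phase_shift = 0) {
  t <- doy - phase_shift
  half <- template$width_days / 2
  rate <- template$width_days / 12
  rise <- .rise(t, template$peak_doy - half, rate)
  ndvi <- phenology_value(template, doy, phase_shift)
  v <- -0.55 * ndvi - 0.05
  if (template$early_water_signal) v <- v + 0.45 * (1 - rise)
  pmin(1, pmax(-1, v))
}

# Invert NDVI/NDWI into 4 consistent bands with a fixed red+NIR brightness.
# Returns list(blue, green, red, nir) for scalar inputs.
.bands_from_indices <- function(ndvi, ndwi) {
  s <- 0.45
  nir <- s * (1 + ndvi) / 2
  red <- s * (1 - ndvi) / 2
  green <- nir * (1 + ndwi) / (1 - pmin(ndwi, 0.95))
  blue <- 0.85 * green
  list(blue = blue, green = green, red = red, nir = nir)
}

#' Generate a multi-year synthetic scene series
#'
#' Tiles the grid with rectangular fields, assigns each field a crop per year
#' (changing with probability `rotation_rate` between consecutive years),
#' draws one global phenology phase shift per year plus a per-field sowing
#' offset and amplitude scale (field identities, constant across years, so
#' that with no rotation and no noise the same pixel's series in two years
#' differs only by the global shift), synthesizes per-date NDVI from the crop
#' templates, inverts it to 4 reflectance bands with additive Gaussian noise,
#' and knocks out observations tile-wise with probability `missing_rate`
#' (masked values are stored as `NaN` and never read downstream).
#'
#' @param config a [scene_config()].
#' @param templates optional named list of [phenology_template()] per class.
#' @return list with `scenes` (named list of `scene_stack`, one per year),
#'   `truth` (a `ground_truth`: `labels` per year, `field_id`, `classes`),
#'   and `phase_shifts` (named numeric, days per year).
#' @export
generate_scene_series <- function(config, templates = NULL) {
  stopifnot(inherits(config, "scene_config"))
  templates <- templates %||% default_phenology_templates(config$crop_classes)
  nr <- config$grid_rows; nc <- config$grid_cols
  n_classes <- length(config$crop_classes)

  # field layout: smallest r x c tiling holding >= n_fields rectangles
  f_r <- max(1L, floor(sqrt(config$n_fields)))
  f_c <- as.integer(ceiling(config$n_fields / f_r))
  if (nr < f_r || nc < f_c)
    stop(sprintf("grid %dx%d too small for %d fields (needs >= %dx%d)",
                 nr, nc, config$n_fields, f_r, f_c))
  row_cut <- unique(round(seq(0, nr, length.out = f_r + 1)))
  col_cut <- unique(round(seq(0, nc, length.out = f_c + 1)))
  if (length(row_cut) != f_r + 1 || length(col_cut) != f_c + 1)
    stop("grid too small for requested field tiling")
  row_band <- findInterval(seq_len(nr) - 1L, row_cut, rightmost.closed = TRUE)
  col_band <- findInterval(seq_len(nc) - 1L, col_cut, rightmost.closed = TRUE)
  field_id <- matrix((rep(row_band, times = nc) - 1L) * f_c +
                       rep(col_band, each = nr), nr, nc)
  n_field <- f_r * f_c

  set.seed(config$seed)
  # crop succession per field
  crops <- matrix(0L, n_field, length(config$years))
  crops[, 1] <- sample.int(n_classes, n_field, replace = TRUE,
                           prob = config$crop_proportions)
  if (length(config$years) > 1) {
    for (y in 2:length(config$years)) {
      rotate <- runif(n_field) < config$rotation_rate
      crops[, y] <- crops[, y - 1]
      if (any(rotate)) {
        for (f in which(rotate)) {
          p <- config$crop_proportions
          p[crops[f, y - 1]] <- 0
          crops[f, y] <- sample.int(n_classes, 1, prob = p / sum(p))
        }
      }
    }
  }
  phase_shifts <- setNames(rnorm(length(config$years), 0,
                                 config$phase_shift_sd_days),
                           config$years)
  field_phase <- rnorm(n_field, 0, config$field_phase_sd_days %||% 0)
  field_amp <- pmax(0.5, 1 + rnorm(n_field, 0, config$field_amp_sd %||% 0))

  doys <- config$doy_grid
  n_d <- length(doys)
  tile <- 16L
  tiles_r <- ceiling(nr / tile); tiles_c <- ceiling(nc / tile)
  pix_tile <- (matrix(rep((seq_len(nr) - 1L) %/% tile, nc), nr, nc)) * tiles_c +
    matrix(rep((seq_len(nc) - 1L) %/% tile, each = nr), nr, nc) + 1L

  scenes <- vector("list", length(config$years))
  labels <- vector("list", length(config$years))
  names(scenes) <- names(labels) <- config$years
  band_names <- c("blue", "green", "red", "nir")

  for (y in seq_along(config$years)) {
    yr <- config$years[y]
    lab <- matrix(crops[as.vector(field_id), y], nr, nc)
    labels[[y]] <- lab
    # per field x date indices (pixels of one field share its crop template
    # modulated by the field's sowing offset and amplitude scale)
    ndvi_fd <- matrix(0, n_field, n_d)
    ndwi_fd <- matrix(0, n_field, n_d)
    for (f in seq_len(n_field)) {
      tmpl <- templates[[config$crop_classes[crops[f, y]]]]
      tmpl$amplitude <- min(tmpl$amplitude * field_amp[f],
                            1 - tmpl$base_ndvi)
      sh <- phase_shifts[y] + field_phase[f]
      ndvi_fd[f, ] <- phenology_value(tmpl, doys, sh)
      ndwi_fd[f, ] <- .ndwi_value(tmpl, doys, sh)
    }
    fid_vec <- as.vector(field_id)
    bands <- array(NA_real_, c(nr, nc, n_d, 4),
                   dimnames = list(NULL, NULL, NULL, band_names))
    valid <- array(TRUE, c(nr, nc, n_d))
    for (d in seq_len(n_d)) {
      b <- .bands_from_indices(ndvi_fd[fid_vec, d], ndwi_fd[fid_vec, d])
      for (k in seq_along(band_names)) {
        v <- b[[band_names[k]]] + rnorm(nr * nc, 0, config$noise_sd)
        bands[, , d, k] <- pmin(1, pmax(0, v))
      }
      bad_tiles <- which(runif(tiles_r * tiles_c) < config$missing_rate)
      if (length(bad_tiles)) {
        bad <- pix_tile %in% bad_tiles
        valid[, , d][bad] <- FALSE
        for (k in seq_along(band_names)) bands[, , d, k][bad] <- NaN
      }
    }
    scenes[[y]] <- new_scene_stack(
      year = yr, dates = doys, bands = bands, valid = valid,
      band_names = band_names,
      transform = list(x0 = 0, y0 = 0, pixel_size = config$pixel_size_m))
  }
  truth <- structure(list(labels = labels, field_id = field_id,
                          classes = config$crop_classes),
                     class = "ground_truth")
  list(scenes = scenes, truth = truth, phase_shifts = phase_shifts)
}

#' Draw labeled sample points from simulated ground truth
#'
#' Emulates a field survey: picks `n_per_class` pixels per crop class for one
#' year, enforcing a minimum pairwise Chebyshev spacing so that the 5x5
#' similarity neighborhoods of distinct samples do not overlap.
#'
#' @param truth `ground_truth` from [generate_scene_series()].
#' @param year year label to sample.
#' @param n_per_class samples requested per class.
#' @param min_spacing_px minimum Chebyshev (chessboard) distance between any
#'   two samples, in pixels.
#' @param seed integer seed.
#' @return a sample table (`data.table`) with columns
#'   `id, year, row, col, class, provenance, similarity` (0-based `row`/`col`).
#' @export
draw_field_samples <- function(truth, year, n_per_class, min_spacing_px = 6,
                               seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  lab <- truth$labels[[as.character(year)]]
  if (is.null(lab)) stop("year not present in ground truth: ", year)
  set.seed(seed)
  acc_r <- integer(0); acc_c <- integer(0); acc_class <- character(0)
  for (cl in seq_along(truth$classes)) {
    idx <- which(lab == cl)
    if (length(idx) < n_per_class)
      warning(sprintf("class %s has only %d eligible pixels (< %d)",
                      truth$classes[cl], length(idx), n_per_class))
    idx <- sample(idx)
    taken <- 0L
    for (i in idx) {
      if (taken >= n_per_class) break
      r <- (i - 1L) %% nrow(lab); c <- (i - 1L) %/% nrow(lab)
      if (length(acc_r) == 0 ||
          all(pmax(abs(acc_r - r), abs(acc_c - c)) >= min_spacing_px)) {
        acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
        acc_class <- c(acc_class, truth$classes[cl])
        taken <- taken + 1L
      }
    }
    if (taken < n_per_class)
      warning(sprintf("class %s: only %d of %d samples placed at spacing %d",
                      truth$classes[cl], taken, n_per_class, min_spacing_px))
  }
  data.table::data.table(
    id = sprintf("s%04d", seq_along(acc_r)), year = as.character(year),
    row = acc_r, col = acc_c, class = acc_class,
    provenance = "field", similarity = NA_real_)
}
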