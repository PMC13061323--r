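#' Burn map state codes
#'
#' Monthly burn maps code each pixel as unburned (0), burned for the first
#' time (1), a repeated detection of a recent scar (2), or unobserved that
#' month because clouds left no valid pre- or post-composite value (255).
#' @export
BURN_STATE <- c(unburned = 0L, burned_new = 1L, burned_repeat = 2L,
                unobserved = 255L)

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- mask[rs - dr, cs - dc, drop = FALSE]
  out
}

# Offsets of the two 3x3 structuring elements: the full square and the
# "circular" (plus/cross) element, the only 3x3 shape distinct from the
# square.
kernel_offsets <- function(shape = c("square", "plus")) {
  shape <- match.arg(shape)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  if (shape == "plus") off <- off[abs(off$dr) + abs(off$dc) <= 1L, ]
  off
}

erode_mask <- function(mask, shape) {
  off <- kernel_offsets(shape)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, off$dr[i], off$dc[i])
  out
}

dilate_mask <- function(mask, shape) {
  off <- kernel_offsets(shape)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[i], off$dc[i])
  out
}

#' Label connected components of a binary map
#'
#' @param mask logical matrix (NA treated as FALSE).
#' @param connectivity 8 (default; diagonal-contiguous scars) or 4.
#' @return integer matrix of component labels, 0 for background.
#' @export
label_patches <- function(mask, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Remove burned patches below the minimum mapping unit
#'
#' Post-classification step (a): connected components of burned pixels
#' smaller than `min_pixels` — including isolated pixels — are reclassified
#' unburned. The default of 156 pixels is the 6.25-ha official minimum
#' mapping unit expressed in 20-m pixels (`mmu_pixels(6.25, grid)`).
#'
#' @param mask logical burned/unburned matrix.
#' @param min_pixels smallest surviving component size (components with
#'   `>= min_pixels` pixels are kept).
#' @param connectivity patch connectivity, 8 or 4.
#' @return logical matrix; never adds burned pixels.
#' @export
remove_small_patches <- function(mask, min_pixels = 156, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  lab <- label_patches(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], max(lab))
  keep <- which(sizes >= min_pixels)
  matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
}

#' Morphological refinement of a burned/unburned map
#'
#' Post-classification step (b): opening with the 3x3 square structuring
#' element (removes pixel-scale noise and weak connections), then closing
#' with the 3x3 "circular" (plus-shaped) element (fills small gaps and
#' smooths outlines).
#'
#' @param mask logical burned/unburned matrix.
#' @return refined logical matrix.
#' @export
morphological_refine <- function(mask) {
  mask[is.na(mask)] <- FALSE
  opened <- dilate_mask(erode_mask(mask, "square"), "square")
  closed <- erode_mask(dilate_mask(opened, "plus"), "plus")
  closed
}

#' Reclassify burned pixels with high post-fire NBR as unburned
#'
#' A vegetated pixel is unlikely to have burned: any burned pixel whose
#' post-fire NBR is strictly greater than the floor (default -0.1) is kept as
#' unburned. Pixels at exactly the floor stay burned.
#'
#' @param mask logical burned/unburned matrix.
#' @param post_nbr NBR grid of the post-fire composite (NA allowed).
#' @param threshold NBR floor, default -0.1.
#' @return logical matrix.
#' @export
apply_nbr_floor <- function(mask, post_nbr, threshold = -0.1) {
  stopifnot(all(dim(mask) == dim(post_nbr)))
  drop <- mask & !is.na(post_nbr) & post_nbr > threshold
  mask & !drop
}

#' Read / write hotspot tables
#'
#' FIRMS-style CSV with columns `date` (or `acq_date`), projected `x`, `y`
#' (or `longitude`/`latitude` taken as map coordinates), and
#' `sensor_resolution_m`.
#'
#' @param path CSV file.
#' @return data.frame with date (Date), x, y, sensor_resolution_m.
#' @export
read_hotspots <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(d)); names(d) <- nm
  if ("acq_date" %in% nm) d$date <- d$acq_date
  if (!"x" %in% nm && "longitude" %in% nm) { d$x <- d$longitude; d$y <- d$latitude }
  if (!all(c("date", "x", "y") %in% names(d)))
    stop("hotspot table needs date/acq_date and x/y columns", call. = FALSE)
  if (!"sensor_resolution_m" %in% names(d)) d$sensor_resolution_m <- 375
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable hotspot dates", call. = FALSE)
  if (!all(is.finite(d$x) & is.finite(d$y)))
    stop("non-finite hotspot coordinates", call. = FALSE)
  d[, c("date", "x", "y", "sensor_resolution_m")]
}

#' @rdname read_hotspots
#' @param hotspots hotspot data.frame.
#' @export
write_hotspots <- function(hotspots, path) {
  utils::write.csv(hotspots, path, row.names = FALSE)
  invisible(path)
}

#' Mask burned patches with no active-fire evidence
#'
#' Post-classification step (c): a burned patch (connected component)
#' survives only if at least one hotspot dated within the window months falls
#' inside the scar or within `buffer_m` of it; otherwise the whole component
#' is reclassified unburned. The distance test is Euclidean, from the hotspot
#' point to the nearest burned-pixel centre (<= `buffer_m`); the scar is
#' buffered, not the point, so hotspot positional uncertainty does not widen
#' the test. The window is anchored at the reference month:
#' `window_months = 4` means the reference month plus the three months before
#' it (the default); 3 gives the two months before plus the reference month.
#'
#' @param mask logical burned/unburned matrix.
#' @param hotspots hotspot data.frame (date, x, y, ...).
#' @param grid the [grid_spec()] of `mask`.
#' @param ref reference month.
#' @param buffer_m scar buffer distance in metres (default 100).
#' @param window_months hotspot window length in months ending at `ref`.
#' @param connectivity patch connectivity.
#' @return logical matrix.
#' @export
mask_with_hotspots <- function(mask, hotspots, grid, ref, buffer_m = 100,
                               window_months = 4, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) return(mask)
  lab <- label_patches(mask, connectivity)
  window <- month_window(ref, 0, window_months)
  rng <- month_date_range(window)
  hs <- hotspots[hotspots$date >= rng[1] & hotspots$date <= rng[2], , drop = FALSE]
  survives <- logical(max(lab))
  if (nrow(hs)) {
    rad_px <- as.integer(ceiling(buffer_m / grid$pixel_size)) + 1L
    for (i in seq_len(nrow(hs))) {
      x <- hs$x[i]; y <- hs$y[i]
      c0 <- floor((x - grid$origin[1]) / grid$pixel_size) + 1
      r0 <- floor((grid$origin[2] - y) / grid$pixel_size) + 1
      rlo <- max(1, r0 - rad_px); rhi <- min(grid$n_rows, r0 + rad_px)
      clo <- max(1, c0 - rad_px); chi <- min(grid$n_cols, c0 + rad_px)
      if (rlo > rhi || clo > chi) next
      rows <- rlo:rhi; cols <- clo:chi
      sub <- lab[rows, cols, drop = FALSE]
      hit <- which(sub > 0L, arr.ind = TRUE)
      if (!nrow(hit)) next
      ctr <- pixel_centres(grid, rows[hit[, 1]], cols[hit[, 2]])
      d2 <- (ctr[, 1] - x)^2 + (ctr[, 2] - y)^2
      survives[unique(sub[hit][d2 <= buffer_m^2])] <- TRUE
    }
  }
  keep <- which(survives)
  matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
}

# ---- burn history -----------------------------------------------------------

#' Create an empty burn history
#'
#' The history tracks, per pixel, the month of the most recent
#' first-detection (`last_new`) and how many first-detections have occurred
#' (`count`). This is sufficient state for the lookback masking rule and for
#' cumulative/extent accounting.
#'
#' @param grid a [grid_spec()].
#' @return object of class `burn_history`.
#' @export
burn_history <- function(grid) {
  structure(list(grid = grid,
                 last_new = matrix(NA_integer_, grid$n_rows, grid$n_cols),
                 count = matrix(0L, grid$n_rows, grid$n_cols)),
            class = "burn_history")
}

#' @export
print.burn_history <- function(x, ...) {
  cat(sprintf("<burn_history> %d pixels ever burned (max %d times), grid %s\n",
              sum(x$count > 0L), max(x$count), format(x$grid)))
  invisible(x)
}

#' Mask repeated detections of recent scars
#'
#' Post-classification step (d): a burn scar stays visible for months, so a
#' pixel already detected as newly burned in any of the `lookback` months
#' before the reference month is flagged `burned_repeat` rather than counted
#' again. Remaining burned pixels become `burned_new` and are appended to the
#' history. The lookback crosses calendar-year boundaries.
#'
#' @param mask logical burned/unburned matrix after the first three filters.
#' @param history a [burn_history()]; months already recorded must precede
#'   `ref`.
#' @param ref reference month.
#' @param lookback window length in months (default 3).
#' @param unobserved optional logical matrix of pixels with no valid
#'   composite this month (coded `unobserved` in the output).
#' @return list with `map` (a `burn_map`) and the updated `history`.
#' @export
mask_repeats <- function(mask, history, ref, lookback = 3, unobserved = NULL) {
  stopifnot(inherits(history, "burn_history"))
  ref_i <- unclass(as_month(ref))
  if (any(history$last_new >= ref_i, na.rm = TRUE))
    stop("burn history contains months at or after the reference month",
         call. = FALSE)
  mask[is.na(mask)] <- FALSE
  recent <- !is.na(history$last_new) &
    history$last_new >= ref_i - as.integer(lookback) & history$last_new < ref_i
  state <- matrix(BURN_STATE[["unburned"]], nrow(mask), ncol(mask))
  state[mask & recent] <- BURN_STATE[["burned_repeat"]]
  new <- mask & !recent
  state[new] <- BURN_STATE[["burned_new"]]
  if (!is.null(unobserved)) state[unobserved & state == BURN_STATE[["unburned"]]] <-
      BURN_STATE[["unobserved"]]
  history$last_new[new] <- ref_i
  history$count[new] <- history$count[new] + 1L
  map <- structure(list(grid = history$grid, state = state,
                        month = as_month(ref)),
                   class = "burn_map")
  list(map = map, history = history)
}

#' @export
print.burn_map <- function(x, ...) {
  px <- pixel_area_ha(x$grid)
  cat(sprintf("<burn_map> %s: %.2f ha newly burned, %.2f ha repeat, %.1f%% unobserved\n",
              format(x$month),
              sum(x$state == BURN_STATE[["burned_new"]]) * px,
              sum(x$state == BURN_STATE[["burned_repeat"]]) * px,
              100 * mean(x$state == BURN_STATE[["unobserved"]])))
  invisible(x)
}

#' Write / read a monthly burn map
#'
#' Stored as a single-band ASCII grid with the state codes of [BURN_STATE].
#' @param map a `burn_map`.
#' @param path file path.
#' @export
write_burn_map <- function(map, path) {
  write_raster(path, map$state + 0, map$grid, nodata = -9999)
  invisible(path)
}

#' @rdname write_burn_map
#' @param month month of the stored map (not recorded in the ASCII grid).
#' @export
read_burn_map <- function(path, month) {
  r <- read_raster(path)
  structure(list(grid = r$grid, state = matrix(as.integer(r$values),
                                               r$grid$n_rows, r$grid$n_cols),
                 month = as_month(month)),
            class = "burn_map")
}
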