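#' Apply per-observation quality masks to a scene stack
#'
#' Pixels flagged invalid (clouds, shadows, other artefacts) are set to NA in
#' every band so that they contribute nothing to any downstream aggregation.
#' Stacks produced by [simulate_stack()] are already masked; this is the
#' entry point for externally assembled stacks.
#'
#' @param stack a `scene_stack`.
#' @return the stack with flagged pixels excluded from all band grids.
#' @export
mask_invalid <- function(stack) {
  stopifnot(inherits(stack, "scene_stack"))
  stack$obs <- lapply(stack$obs, function(o) {
    if (is.null(o$valid)) stop("observation is missing its validity mask",
                               call. = FALSE)
    o$bands <- lapply(o$bands, function(b) { b[!o$valid] <- NA_real_; b })
    o
  })
  stack
}

#' Aggregate a 10-m band grid to 20 m by 2x2 block mean
#'
#' Each coarse value is the mean of its valid children; the coarse pixel is
#' valid iff at least one of the four children is valid.
#'
#' @param values numeric matrix at 10 m; NA marks invalid cells. Dimensions
#'   must be exactly twice the target grid (even).
#' @return numeric matrix at half the resolution (NA where no child valid).
#' @export
resample_10m_to_20m <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  if (nr %% 2L || nc %% 2L)
    stop("10-m grid must have even dimensions to aggregate 2x2", call. = FALSE)
  q <- function(ro, co) values[seq(1L + ro, nr, 2L), seq(1L + co, nc, 2L), drop = FALSE]
  a <- q(0L, 0L); b <- q(0L, 1L); c <- q(1L, 0L); d <- q(1L, 1L)
  cnt <- (!is.na(a)) + (!is.na(b)) + (!is.na(c)) + (!is.na(d))
  z <- function(m) { m[is.na(m)] <- 0; m }
  s <- z(a) + z(b) + z(c) + z(d)
  out <- s / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Build a cloud-free median composite for a month window
#'
#' Per pixel and per band, the composite is the median of all valid
#' observations dated within the window (whole calendar months, first to last
#' day). Even observation counts average the two central values. A pixel with
#' no valid observation in the window is invalid in the composite. The
#' pre-fire composite of a reference month uses `month_window(ref, 1, 3)`;
#' the post-fire composite uses the reference month alone.
#'
#' @param stack a `scene_stack`.
#' @param months window months (`month_key` or `"YYYY-MM"` strings).
#' @param kind `"pre"` or `"post"` (metadata only).
#' @return object of class `burn_composite`: `grid`, per-band median grids in
#'   `bands`, `nbr`, `valid`, `window`, `kind`.
#' @export
build_composite <- function(stack, months, kind = c("pre", "post")) {
  stopifnot(inherits(stack, "scene_stack"))
  kind <- match.arg(kind)
  months <- as_month(months)
  rng <- month_date_range(months)
  dates <- as.Date(vapply(stack$obs, function(o) as.character(o$date), ""))
  sel <- which(dates >= rng[1] & dates <= rng[2])
  if (!length(sel))
    stop(sprintf("no observations in compositing window %s..%s",
                 format(months[1]), format(months[length(months)])),
         call. = FALSE)
  grid <- stack$grid
  npx <- grid$n_rows * grid$n_cols
  bands <- stack$band_set
  med <- vector("list", length(bands)); names(med) <- bands
  for (b in bands) {
    m <- matrix(NA_real_, npx, length(sel))
    for (j in seq_along(sel)) m[, j] <- as.vector(stack$obs[[sel[j]]]$bands[[b]])
    med[[b]] <- matrix(.row_medians_cpp(m), grid$n_rows, grid$n_cols)
  }
  valid <- Reduce(`&`, lapply(med, function(x) !is.na(x)))
  # a pixel valid in one band of an observation is valid in all (one mask per
  # observation), so any-band and all-band agreement is by construction
  comp <- structure(list(grid = grid, bands = med, nbr = NULL, valid = valid,
                         window = months, kind = kind),
                    class = "burn_composite")
  comp$nbr <- compute_nbr(comp)
  comp
}

#' Normalized Burn Ratio of a composite
#'
#' NBR = (NIR - SWIR) / (NIR + SWIR), by default with the native-20-m pair
#' B8A (NIR) and B12 (SWIR2). Pixels where the denominator is zero (or either
#' band invalid) are invalid (NA), never NaN.
#'
#' @param composite a `burn_composite` (or any list with a `bands` element).
#' @param nir,swir band names used for the ratio.
#' @return numeric NBR matrix in \[-1, 1\] where defined.
#' @export
compute_nbr <- function(composite, nir = "B8A", swir = "B12") {
  a <- composite$bands[[nir]]; b <- composite$bands[[swir]]
  if (is.null(a) || is.null(b))
    stop("composite lacks bands ", nir, "/", swir, call. = FALSE)
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' @export
print.burn_composite <- function(x, ...) {
  cat(sprintf("<burn_composite> %s window %s..%s, %d bands + NBR, %.1f%% valid, grid %s\n",
              x$kind, format(x$window[1]), format(x$window[length(x$window)]),
              length(x$bands), 100 * mean(x$valid), format(x$grid)))
  invisible(x)
}
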