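#' Write a scene stack to a directory of ASCII grids plus a manifest
#'
#' One `.asc` file per observation and band (`obs<k>_<band>.asc`) and a
#' validity grid (`obs<k>_valid.asc`), indexed by `manifest.csv` (columns
#' date, band, path). [read_scene_stack()] inverts the layout.
#'
#' @param stack a `scene_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "scene_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_along(stack$obs)) {
    o <- stack$obs[[k]]
    for (b in stack$band_set) {
      f <- sprintf("obs%03d_%s.asc", k, b)
      write_raster(file.path(dir, f), o$bands[[b]], stack$grid)
      rows[[length(rows) + 1L]] <- data.frame(date = as.character(o$date),
                                              band = b, path = f)
    }
    f <- sprintf("obs%03d_valid.asc", k)
    write_raster(file.path(dir, f), o$valid + 0, stack$grid)
    rows[[length(rows) + 1L]] <- data.frame(date = as.character(o$date),
                                            band = "valid", path = f)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene_stack
#' @param expected_grid optional [grid_spec()] every raster must match.
#' @export
read_scene_stack <- function(dir, expected_grid = NULL) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  dates <- unique(man$date)
  grid <- NULL
  obs <- lapply(dates, function(d) {
    sub <- man[man$date == d, ]
    bands <- list()
    valid <- NULL
    for (i in seq_len(nrow(sub))) {
      r <- read_raster(file.path(dir, sub$path[i]), expected_grid)
      grid <<- r$grid
      if (sub$band[i] == "valid") valid <- !is.na(r$values) & r$values > 0
      else bands[[sub$band[i]]] <- r$values
    }
    if (is.null(valid)) valid <- Reduce(`&`, lapply(bands, function(b) !is.na(b)))
    for (b in names(bands)) bands[[b]][!valid] <- NA_real_
    list(date = as.Date(d), bands = bands[band_set()], valid = valid)
  })
  structure(list(grid = grid, band_set = band_set(), obs = obs),
            class = "scene_stack")
}

#' Write a composite as per-band ASCII grids plus a manifest
#'
#' Writes the ten band medians, the NBR grid and the validity grid, with the
#' window and kind recorded in `manifest.csv`.
#'
#' @param composite a `burn_composite`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_composite <- function(composite, dir) {
  stopifnot(inherits(composite, "burn_composite"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  grids <- c(composite$bands, list(NBR = composite$nbr,
                                   valid = composite$valid + 0))
  for (b in names(grids)) {
    f <- paste0(b, ".asc")
    write_raster(file.path(dir, f), grids[[b]] + 0, composite$grid)
    rows[[length(rows) + 1L]] <- data.frame(
      band = b, path = f, kind = composite$kind,
      window_start = format(composite$window[1]),
      window_end = format(composite$window[length(composite$window)]))
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
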