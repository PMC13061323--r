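#' Grid specification for a raster on a regular map grid
#'
#' A `grid_spec` pins every raster in the processing chain to one common
#' geometry: number of rows and columns, square pixel size in metres, the map
#' coordinates of the top-left corner, and an opaque CRS label. All area
#' arithmetic in the package goes through pixel counts times
#' [pixel_area_ha()].
#'
#' Convention: rows/columns are 1-based in R, row 1 is the northern edge; the
#' centre of pixel (r, c) sits at
#' `x = origin[1] + (c - 0.5) * pixel_size`, `y = origin[2] - (r - 0.5) * pixel_size`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pixel_size square pixel edge length in metres (> 0); default 20.
#' @param origin numeric length-2, map coordinates (x, y) of the top-left
#'   corner of the top-left pixel.
#' @param crs_label free-form coordinate reference system label.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 20, origin = c(0, 0),
                      crs_label = "local-metric") {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1, n_cols >= 1, pixel_size > 0,
            length(origin) == 2L, is.finite(origin))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin),
                 crs_label = as.character(crs_label)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels @ %g m (%.4g ha total), origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size,
              x$n_rows * x$n_cols * pixel_area_ha(x),
              x$origin[1], x$origin[2], x$crs_label))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm origin(%g,%g) crs=%s", x$n_rows, x$n_cols, x$pixel_size,
          x$origin[1], x$origin[2], x$crs_label)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: [%s] vs [%s]",
                 what, format(a), format(b)), call. = FALSE)
  invisible(TRUE)
}

#' Pixel area in hectares
#'
#' @param grid a [grid_spec()].
#' @return area of one pixel in hectares (`pixel_size^2 / 1e4`); 0.04 ha for
#'   a 20-m pixel.
#' @export
pixel_area_ha <- function(grid) {
  grid$pixel_size^2 / 1e4
}

#' Minimum mapping unit expressed in pixels
#'
#' Converts an area threshold in hectares to the equivalent whole-pixel count
#' on a given grid (floor). At 20 m the Indonesian official 6.25-ha minimum
#' mapping unit corresponds to 156 pixels.
#'
#' @param mmu_ha minimum mapping unit in hectares.
#' @param grid a [grid_spec()].
#' @return integer pixel count.
#' @export
mmu_pixels <- function(mmu_ha, grid) {
  as.integer(floor(mmu_ha / pixel_area_ha(grid)))
}

#' Map coordinates of pixel centres
#'
#' @param grid a [grid_spec()].
#' @param rows,cols 1-based pixel indices (vectorised, recycled together).
#' @return two-column matrix of (x, y) centre coordinates.
#' @export
pixel_centres <- function(grid, rows, cols) {
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$pixel_size,
        y = grid$origin[2] - (rows - 0.5) * grid$pixel_size)
}

#' Pixel indices containing map coordinates
#'
#' Points outside the grid get NA indices.
#'
#' @param grid a [grid_spec()].
#' @param x,y map coordinates.
#' @return two-column integer matrix (row, col).
#' @export
map_to_pixel <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$pixel_size) + 1
  row <- floor((grid$origin[2] - y) / grid$pixel_size) + 1
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---- calendar months --------------------------------------------------------

#' Calendar-month keys
#'
#' Months are handled as whole calendar months. The user-facing form is the
#' string `"YYYY-MM"`; internally a month is an integer index
#' `year * 12 + (month - 1)`, which makes ordering and wrap-around arithmetic
#' trivial. All functions below are vectorised.
#'
#' @param x months as `"YYYY-MM"` strings (also accepts `"YYYY-MM-DD"` or
#'   `Date`, which are truncated to the month).
#' @return integer month index vector (class `month_key`).
#' @export
as_month <- function(x) {
  if (inherits(x, "month_key")) return(x)
  if (inherits(x, "Date")) {
    y <- as.integer(format(x, "%Y")); m <- as.integer(format(x, "%m"))
  } else if (is.character(x)) {
    ok <- grepl("^\\d{4}-\\d{2}(-\\d{2})?$", x)
    if (!all(ok | is.na(x))) stop("months must be 'YYYY-MM' strings", call. = FALSE)
    y <- as.integer(substr(x, 1, 4)); m <- as.integer(substr(x, 6, 7))
  } else if (is.numeric(x)) {
    return(structure(as.integer(x), class = "month_key"))
  } else stop("cannot interpret months of class ", class(x)[1], call. = FALSE)
  if (any(m < 1 | m > 12, na.rm = TRUE)) stop("month out of 1..12", call. = FALSE)
  structure(y * 12L + (m - 1L), class = "month_key")
}

#' @rdname as_month
#' @param year,month integer year and month-of-year (1-12).
#' @export
month_key <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  structure(as.integer(year) * 12L + (as.integer(month) - 1L),
            class = "month_key")
}

#' @export
format.month_key <- function(x, ...) {
  sprintf("%04d-%02d", unclass(x) %/% 12L, unclass(x) %% 12L + 1L)
}

#' @export
print.month_key <- function(x, ...) { print(format(x)); invisible(x) }

#' @export
`[.month_key` <- function(x, i) structure(unclass(x)[i], class = "month_key")

#' @export
as.character.month_key <- function(x, ...) format(x)

month_add <- function(m, k) structure(unclass(as_month(m)) + as.integer(k),
                                      class = "month_key")

month_of_year <- function(m) unclass(as_month(m)) %% 12L + 1L
year_of <- function(m) unclass(as_month(m)) %/% 12L

#' Consecutive-month windows anchored at a reference month
#'
#' Returns `length` consecutive calendar months ending `offset_back` months
#' before the reference month (`offset_back = 0` means the window ends at the
#' reference month itself). The pre-fire compositing window is
#' `month_window(ref, 1, 3)` — the three months preceding the reference month
#' — and the default hotspot window is `month_window(ref, 0, 4)`.
#'
#' @param ref reference month (`"YYYY-MM"` or `month_key`).
#' @param offset_back months between the window end and `ref`.
#' @param length window length in months (>= 1).
#' @return `month_key` vector of `length` consecutive months, ascending.
#' @export
month_window <- function(ref, offset_back, length) {
  stopifnot(length >= 1, offset_back >= 0)
  ref <- as_month(ref)
  stopifnot(base::length(ref) == 1L)
  last <- unclass(ref) - as.integer(offset_back)
  structure(seq.int(last - as.integer(length) + 1L, last), class = "month_key")
}

#' Date range covered by a set of months
#'
#' @param months `month_key` vector.
#' @return `Date` vector of length 2: first day of the earliest month, last
#'   day of the latest month.
#' @export
month_date_range <- function(months) {
  months <- as_month(months)
  lo <- min(unclass(months)); hi <- max(unclass(months))
  first <- as.Date(sprintf("%04d-%02d-01", lo %/% 12L, lo %% 12L + 1L))
  nxt <- as.Date(sprintf("%04d-%02d-01", (hi + 1L) %/% 12L, (hi + 1L) %% 12L + 1L))
  c(first, nxt - 1)
}

# ---- raster I/O (Esri ASCII grid) -------------------------------------------

#' Read a single-band raster from an Esri ASCII grid file
#'
#' The chain exchanges rasters as Esri ASCII grids (`.asc`): a plain-text,
#' georeferenced, nodata-aware format readable by all mainstream GIS
#' software. An optional sidecar `<path>.prj` text file carries the CRS
#' label. Nodata cells are translated into `valid = FALSE`; values are never
#' carried as sentinels inside computations.
#'
#' @param path file to read.
#' @param expected_grid optional [grid_spec()]; a mismatch raises an
#'   alignment error naming both grids.
#' @return list with `values` (numeric matrix, NA where invalid), `valid`
#'   (logical matrix) and `grid` (a [grid_spec()]).
#' @export
read_raster <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an Esri ASCII grid (missing header keys): ", path, call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  ps <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - ps / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - ps / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = lines[seq.int(i, length(lines))], what = numeric(),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("raster %s: expected %d values, found %d", path, nr * nc,
                 length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  valid <- m != nodata
  m[!valid] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "unknown"
  grid <- grid_spec(nr, nc, ps, origin = c(xll, yll + nr * ps), crs_label = crs)
  if (!is.null(expected_grid)) check_same_grid(grid, expected_grid,
                                               sprintf("'%s' and expected grid", path))
  list(values = m, valid = valid, grid = grid)
}

#' Write a single-band raster as an Esri ASCII grid file
#'
#' Inverse of [read_raster()]: integer grids round-trip bit-exactly and
#' floating grids to full double precision (values are printed with 17
#' significant digits). NA cells are written as the nodata value.
#'
#' @param path output file.
#' @param values numeric matrix matching `grid` dimensions; NA means nodata.
#' @param grid a [grid_spec()].
#' @param nodata nodata sentinel written to the file header (default -9999);
#'   must not collide with finite data values.
#' @return `path`, invisibly.
#' @export
write_raster <- function(path, values, grid, nodata = -9999) {
  stopifnot(is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop(sprintf("values are %dx%d but grid is %dx%d", nrow(values),
                 ncol(values), grid$n_rows, grid$n_cols), call. = FALSE)
  if (any(values == nodata, na.rm = TRUE))
    stop("data contains the nodata sentinel ", nodata, call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2] - grid$n_rows * grid$pixel_size),
               sprintf("cellsize %.10g", grid$pixel_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  out <- values
  out[is.na(out)] <- nodata
  writeLines(apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  if (!identical(grid$crs_label, "unknown"))
    writeLines(grid$crs_label, paste0(path, ".prj"))
  invisible(path)
}
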