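#' Run configuration for the monthly chain
#'
#' Gathers every named threshold of the processing chain in one auditable
#' place: minimum mapping unit (in pixels), NBR floor, hotspot buffer and
#' window, repeat-masking lookback, pre-fire window length, patch
#' connectivity, and the classifier configuration.
#'
#' @param min_pixels minimum mapping unit in pixels (156 = 6.25 ha at 20 m).
#' @param nbr_floor post-fire NBR above which a pixel is kept unburned.
#' @param buffer_m scar buffer for the hotspot test, metres.
#' @param hotspot_window_months hotspot window ending at the reference month.
#' @param lookback repeat-masking lookback, months.
#' @param pre_window_months pre-fire compositing window length, months.
#' @param connectivity patch connectivity (8 or 4).
#' @param rf an [rf_config()].
#' @param verbose log per-stage pixel-count deltas with [message()].
#' @return list of class `run_config`.
#' @export
run_config <- function(min_pixels = 156, nbr_floor = -0.1, buffer_m = 100,
                       hotspot_window_months = 4, lookback = 3,
                       pre_window_months = 3, connectivity = 8,
                       rf = rf_config(), verbose = FALSE) {
  stopifnot(min_pixels >= 1, nbr_floor >= -1, nbr_floor <= 1, buffer_m >= 0,
            hotspot_window_months >= 1, lookback >= 0, pre_window_months >= 1,
            connectivity %in% c(4, 8))
  structure(list(min_pixels = as.integer(min_pixels), nbr_floor = nbr_floor,
                 buffer_m = buffer_m,
                 hotspot_window_months = as.integer(hotspot_window_months),
                 lookback = as.integer(lookback),
                 pre_window_months = as.integer(pre_window_months),
                 connectivity = as.integer(connectivity), rf = rf,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

log_stage <- function(cfg, ref, stage, n_before, n_after) {
  if (cfg$verbose)
    message(sprintf("[%s] %-22s burned px %d -> %d (%+d)",
                    format(as_month(ref)), stage, n_before, n_after,
                    n_after - n_before))
}

#' Process one reference month
#'
#' Composes the full chain for a reference month: pre- and post-fire median
#' composites, 22-feature assembly, random-forest prediction, then the four
#' post-classification filters in order — minimum-mapping-unit removal,
#' morphological refinement, NBR floor, hotspot masking, repeat masking.
#' Pixels invalid in either composite are unobservable this month and coded
#' `unobserved`.
#'
#' @param stack a `scene_stack` covering the pre and post windows.
#' @param hotspots hotspot data.frame.
#' @param history a [burn_history()], updated and returned.
#' @param ref reference month.
#' @param model a trained `burn_rf`.
#' @param cfg a [run_config()].
#' @return list with `map` (a `burn_map`), `history`, and `counts` (burned
#'   pixels after each stage, for auditing).
#' @export
run_month <- function(stack, hotspots, history, ref, model, cfg = run_config()) {
  ref <- as_month(ref)
  pre <- build_composite(stack, month_window(ref, 1, cfg$pre_window_months), "pre")
  post <- build_composite(stack, ref, "post")
  fs <- assemble_features(pre, post)
  raw <- rf_predict(model, fs)
  burned <- !is.na(raw) & raw == 0L
  counts <- c(raw = sum(burned))
  log_stage(cfg, ref, "rf_predict", NA_integer_, counts[["raw"]])

  m1 <- remove_small_patches(burned, cfg$min_pixels, cfg$connectivity)
  counts["small_patches"] <- sum(m1)
  log_stage(cfg, ref, "remove_small_patches", sum(burned), sum(m1))

  m2 <- morphological_refine(m1)
  counts["morphology"] <- sum(m2)
  log_stage(cfg, ref, "morphological_refine", sum(m1), sum(m2))

  m3 <- apply_nbr_floor(m2, post$nbr, cfg$nbr_floor)
  counts["nbr_floor"] <- sum(m3)
  log_stage(cfg, ref, "apply_nbr_floor", sum(m2), sum(m3))

  m4 <- mask_with_hotspots(m3, hotspots, stack$grid, ref, cfg$buffer_m,
                           cfg$hotspot_window_months, cfg$connectivity)
  counts["hotspots"] <- sum(m4)
  log_stage(cfg, ref, "mask_with_hotspots", sum(m3), sum(m4))

  res <- mask_repeats(m4, history, ref, cfg$lookback, unobserved = !fs$valid)
  counts["burned_new"] <- sum(res$map$state == BURN_STATE[["burned_new"]])
  log_stage(cfg, ref, "mask_repeats", sum(m4), counts[["burned_new"]])
  list(map = res$map, history = res$history, counts = counts)
}

#' Process a contiguous range of months
#'
#' Threads the burn history through the months in calendar order. Months
#' whose compositing windows have no observations are skipped with a warning
#' (or abort when `on_missing = "fail"`).
#'
#' @param stack a `scene_stack`.
#' @param hotspots hotspot data.frame.
#' @param months months to process, ascending.
#' @param model a trained `burn_rf`.
#' @param cfg a [run_config()].
#' @param history optional starting [burn_history()].
#' @param on_missing `"skip"` or `"fail"`.
#' @return list with `maps` (named list of `burn_map`s), `history`, `counts`
#'   (per-month stage counts).
#' @export
run_range <- function(stack, hotspots, months, model, cfg = run_config(),
                      history = NULL, on_missing = c("skip", "fail")) {
  on_missing <- match.arg(on_missing)
  months <- as_month(months)
  stopifnot(all(diff(unclass(months)) == 1L))
  if (is.null(history)) history <- burn_history(stack$grid)
  maps <- list(); counts <- list()
  for (i in seq_along(months)) {
    ref <- months[i]
    res <- tryCatch(
      run_month(stack, hotspots, history, ref, model, cfg),
      error = function(e) {
        if (on_missing == "fail") stop(e)
        warning(sprintf("skipping %s: %s", format(ref), conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    history <- res$history
    maps[[format(ref)]] <- res$map
    counts[[format(ref)]] <- res$counts
  }
  list(maps = maps, history = history, counts = counts)
}

#' Summarise a stack of monthly burn maps
#'
#' Computes the accounting of a multi-month run: per-month newly burned area,
#' the cumulative monthly series, the per-pixel burn-count grid, and the
#' totals — area burned exactly once, area burned multiple times, total
#' burned extent (each pixel counted once; extent = once + multiple), and
#' cumulative burned area (each pixel counted once per first-detection;
#' cumulative = sum over k of k * area burned k times >= extent).
#'
#' @param maps list of `burn_map` objects on one grid.
#' @return object of class `burn_summary`.
#' @export
summarize_burn_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  px <- pixel_area_ha(grid)
  count <- matrix(0L, grid$n_rows, grid$n_cols)
  monthly <- numeric(length(maps))
  mk <- integer(length(maps))
  for (i in seq_along(maps)) {
    check_same_grid(maps[[i]]$grid, grid, "burn maps")
    new <- maps[[i]]$state == BURN_STATE[["burned_new"]]
    count <- count + new
    monthly[i] <- sum(new) * px
    mk[i] <- unclass(maps[[i]]$month)
  }
  ord <- order(mk)
  monthly <- monthly[ord]
  months <- structure(mk[ord], class = "month_key")
  kmax <- max(count)
  area_by_k <- if (kmax > 0) vapply(seq_len(kmax),
                                    function(k) sum(count == k) * px,
                                    numeric(1)) else numeric()
  once <- if (kmax >= 1) area_by_k[1] else 0
  multiple <- if (kmax >= 2) sum(area_by_k[-1]) else 0
  structure(list(grid = grid, months = months, monthly_area_ha = monthly,
                 cumulative_series_ha = cumsum(monthly),
                 burn_count = count, area_by_times_burned = area_by_k,
                 area_once_ha = once, area_multiple_ha = multiple,
                 total_extent_ha = once + multiple,
                 cumulative_area_ha = if (kmax > 0)
                   sum(seq_len(kmax) * area_by_k) else 0),
            class = "burn_summary")
}

#' @export
print.burn_summary <- function(x, ...) {
  cat(sprintf("<burn_summary> %d months (%s..%s)\n", length(x$months),
              format(x$months[1]), format(x$months[length(x$months)])))
  cat(sprintf("  burned once:      %10.2f ha\n", x$area_once_ha))
  cat(sprintf("  burned multiple:  %10.2f ha\n", x$area_multiple_ha))
  cat(sprintf("  total extent:     %10.2f ha\n", x$total_extent_ha))
  cat(sprintf("  cumulative:       %10.2f ha\n", x$cumulative_area_ha))
  invisible(x)
}

#' Aggregate burned pixels to a coarse burned-fraction grid
#'
#' Each coarse cell is the burned-pixel count divided by the number of
#' observed (non-`unobserved`) pixels in its `factor` x `factor` block —
#' e.g. factor 50 turns a 20-m map into a 1-km burned fraction. Grids whose
#' dimensions are not divisible by `factor` are padded with unobserved
#' pixels. Blocks with no observed pixel are NA, not 0.
#'
#' @param map a `burn_map`, or a logical burned matrix.
#' @param factor aggregation factor (default 50).
#' @param include_repeat count `burned_repeat` pixels as burned.
#' @return numeric matrix of fractions in \[0, 1\] (NA where unobserved).
#' @export
aggregate_fraction <- function(map, factor = 50, include_repeat = FALSE) {
  if (inherits(map, "burn_map")) {
    burned <- map$state == BURN_STATE[["burned_new"]]
    if (include_repeat) burned <- burned | map$state == BURN_STATE[["burned_repeat"]]
    observed <- map$state != BURN_STATE[["unobserved"]]
  } else {
    burned <- map & !is.na(map)
    observed <- !is.na(map)
  }
  nr <- nrow(burned); nc <- ncol(burned)
  NR <- ceiling(nr / factor) * factor; NC <- ceiling(nc / factor) * factor
  pad <- function(m) { out <- matrix(FALSE, NR, NC); out[1:nr, 1:nc] <- m; out }
  burned <- pad(burned); observed <- pad(observed)
  blocksum <- function(m) {
    g1 <- rowsum(m + 0, rep(seq_len(NR / factor), each = factor))
    t(rowsum(t(g1), rep(seq_len(NC / factor), each = factor)))
  }
  b <- blocksum(burned); o <- blocksum(observed)
  out <- b / o
  out[o == 0] <- NA_real_
  out
}

#' Burned area inside a zone mask
#'
#' @param maps list of `burn_map`s (or one map); newly burned pixels are
#'   counted once per map.
#' @param zone logical matrix (the zone membership), on the maps' grid.
#' @return hectares of newly burned area inside the zone.
#' @export
zonal_area <- function(maps, zone) {
  if (inherits(maps, "burn_map")) maps <- list(maps)
  grid <- maps[[1]]$grid
  if (!all(dim(zone) == c(grid$n_rows, grid$n_cols)))
    stop(sprintf("zone mask is %dx%d but maps are %dx%d", nrow(zone),
                 ncol(zone), grid$n_rows, grid$n_cols), call. = FALSE)
  px <- pixel_area_ha(grid)
  total <- 0
  for (bm in maps) {
    check_same_grid(bm$grid, grid, "burn maps")
    total <- total + sum(bm$state == BURN_STATE[["burned_new"]] & zone) * px
  }
  total
}
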