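#' Reference spectra for the synthetic scene classes
#'
#' Mean surface reflectance per 20-m band for the three land states the
#' generator emulates: photosynthetic vegetation, fresh char/ash (burned) and
#' wet exposed soil (the "confuser" state of mechanically cleared peatland).
#' The binding contract is the NBR behaviour — vegetation near +0.5, fresh
#' burn below -0.2, wet soil burn-like in NBR yet spectrally distinct in the
#' visible/red-edge bands so a classifier given hard negatives can separate
#' it.
#'
#' @return numeric matrix, rows = classes, columns = the ten bands.
#' @export
class_spectra <- function() {
  bands <- band_set()
  m <- rbind(
    vegetation = c(0.030, 0.050, 0.040, 0.080, 0.200, 0.280, 0.320, 0.360, 0.180, 0.120),
    burned     = c(0.040, 0.050, 0.060, 0.070, 0.080, 0.080, 0.080, 0.080, 0.200, 0.160),
    wet_soil   = c(0.060, 0.080, 0.100, 0.115, 0.125, 0.130, 0.130, 0.130, 0.250, 0.210)
  )
  colnames(m) <- bands
  m
}

#' The ten 20-m-capable Sentinel-2-like bands used by the chain
#'
#' The three 60-m bands (B1, B9, B10) are excluded throughout.
#' @return character vector of band names in canonical order.
#' @export
band_set <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
}

#' Configuration of the synthetic scene generator
#'
#' Bundles every knob of the simulated study conditions: grid geometry,
#' months covered, revisit interval, per-pixel cloud probability, burn
#' events (count, size range in hectares, month assignment), the exponential
#' NBR regrowth half-life, wet-soil confuser patches, and the hotspot
#' emission model (density per burned km2, positional jitter equal to the
#' detecting sensor's resolution, and a per-event miss probability).
#'
#' @param grid a [grid_spec()].
#' @param months months simulated (`"YYYY-MM"` strings or `month_key`).
#' @param revisit_days days between successive observations (default 5).
#' @param cloud_prob probability that a pixel of an observation is invalid.
#' @param n_burn_events number of burn events.
#' @param burn_size_range length-2 numeric, event sizes in hectares.
#' @param burn_month_assignment optional vector of months, one per event;
#'   `NULL` assigns events to months at random (months with a full pre-fire
#'   window available are preferred).
#' @param regrowth_halflife_months half-life of the post-burn recovery of the
#'   spectral burn signal, in months.
#' @param n_confusers number of wet-soil confuser patches; each switches from
#'   vegetation to wet soil in a random onset month and persists.
#' @param hotspot_density expected hotspot points per burned km2 per event.
#' @param hotspot_jitter_m positional jitter radius of hotspots in metres
#'   (375 for a VIIRS-like sensor, 1000 for a MODIS-like sensor).
#' @param hotspot_miss_prob probability an event emits no hotspot at all.
#' @param noise_sd Gaussian reflectance noise (per band, per observation).
#' @param seed integer seed; one stream drives all sampling.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid = grid_spec(128, 128),
                       months = month_window("2019-12", 0, 12),
                       revisit_days = 5,
                       cloud_prob = 0.2,
                       n_burn_events = 3,
                       burn_size_range = c(10, 80),
                       burn_month_assignment = NULL,
                       regrowth_halflife_months = 4,
                       n_confusers = 2,
                       hotspot_density = 10,
                       hotspot_jitter_m = 375,
                       hotspot_miss_prob = 0,
                       noise_sd = 0.012,
                       seed = 1L) {
  months <- as_month(months)
  stopifnot(cloud_prob >= 0, cloud_prob <= 1,
            hotspot_miss_prob >= 0, hotspot_miss_prob <= 1,
            revisit_days >= 1, n_burn_events >= 0, n_confusers >= 0,
            length(burn_size_range) == 2L, all(burn_size_range > 0),
            regrowth_halflife_months > 0, noise_sd >= 0)
  if (!is.null(burn_month_assignment)) {
    burn_month_assignment <- as_month(burn_month_assignment)
    stopifnot(length(burn_month_assignment) == n_burn_events)
    if (!all(unclass(burn_month_assignment) %in% unclass(months)))
      stop("burn months must be a subset of the simulated months", call. = FALSE)
  }
  structure(list(grid = grid, months = months, revisit_days = revisit_days,
                 cloud_prob = cloud_prob, n_burn_events = n_burn_events,
                 burn_size_range = burn_size_range,
                 burn_month_assignment = burn_month_assignment,
                 regrowth_halflife_months = regrowth_halflife_months,
                 n_confusers = n_confusers, hotspot_density = hotspot_density,
                 hotspot_jitter_m = hotspot_jitter_m,
                 hotspot_miss_prob = hotspot_miss_prob,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Burn-signal severity at a given lag since burning
#'
#' The generator's closed-form regrowth model: in the burn month severity is
#' 1 (pure char/ash spectrum) and it halves every `halflife` months as
#' vegetation recovers. Band means at lag t are
#' `vegetation + s(t) * (burned - vegetation)`.
#'
#' @param months_since_burn non-negative lag in whole months (0 = burn month).
#' @param halflife regrowth half-life in months.
#' @return severity in (0, 1].
#' @export
burn_severity <- function(months_since_burn, halflife) {
  0.5^(months_since_burn / halflife)
}

#' Noise-free NBR trajectory implied by the generator's spectra
#'
#' Evaluates NBR (B8A vs B12) of the severity-mixed mean spectrum at the
#' given lags; the synthetic stack's event pixels fluctuate around this curve.
#'
#' @inheritParams burn_severity
#' @return numeric vector of NBR values.
#' @export
expected_nbr_trajectory <- function(months_since_burn, halflife) {
  sp <- class_spectra()
  s <- burn_severity(months_since_burn, halflife)
  b8a <- sp["vegetation", "B8A"] + s * (sp["burned", "B8A"] - sp["vegetation", "B8A"])
  b12 <- sp["vegetation", "B12"] + s * (sp["burned", "B12"] - sp["vegetation", "B12"])
  (b8a - b12) / (b8a + b12)
}

# Grow a connected patch of target_px pixels by randomised dilation from a
# seed pixel, avoiding `forbidden` cells. Returns linear pixel indices or
# NULL if growth stalls.
grow_patch <- function(forbidden, target_px, grid) {
  nr <- grid$n_rows; nc <- grid$n_cols
  free <- which(!forbidden)
  if (!length(free)) return(NULL)
  seed <- free[sample.int(length(free), 1L)]
  member <- logical(nr * nc)
  member[seed] <- TRUE
  frontier <- seed
  n <- 1L
  neigh <- function(idx) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    rr <- c(r - 1L, r + 1L, r, r); cc <- c(c, c, c - 1L, c + 1L)
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  while (n < target_px && length(frontier)) {
    cand <- unique(unlist(lapply(frontier, neigh)))
    cand <- cand[!member[cand] & !forbidden[cand]]
    if (!length(cand)) return(NULL)
    # accept most of the frontier each round: scars are compact at the
    # pixel scale, with mildly irregular edges
    take <- min(length(cand), max(1L, round(length(cand) * 0.9)), target_px - n)
    add <- cand[sample.int(length(cand), take)]
    member[add] <- TRUE
    n <- n + take
    frontier <- add
  }
  if (n < target_px) return(NULL)
  which(member)
}

# Chebyshev-style disc dilation of a logical matrix by radius_px using
# Euclidean offsets; used to keep confusers clear of event/hotspot zones.
dilate_by_disc <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  out <- mask
  for (dr in -radius_px:radius_px) for (dc in -radius_px:radius_px) {
    if (dr * dr + dc * dc > radius_px * radius_px) next
    out <- out | shift_mask(mask, dr, dc)
  }
  out
}

#' Simulate a Sentinel-2-like scene stack with ground truth
#'
#' Generates a time-indexed multiband reflectance stack with per-observation
#' validity masks, a table of fire hotspots, and the ground truth needed to
#' score every downstream stage. Unburned vegetation has NBR fluctuating
#' around +0.5; in its burn month an event footprint drops below -0.2 and
#' recovers exponentially with the configured half-life; wet-soil confusers
#' acquire a burn-like NBR at their onset month but never emit hotspots;
#' clouds set validity to FALSE. Hotspots are emitted from burned pixels
#' during the burn month with positional jitter bounded by
#' `hotspot_jitter_m`. Deterministic for a fixed `seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with components `stack` (a `scene_stack`), `hotspots` (a
#'   hotspot data.frame: date, x, y, sensor_resolution_m), and `truth` (a
#'   `truth_set`: `event_id` and `confuser_id` label grids, `burn_count`
#'   grid, `events` and `confusers` data.frames, `hotspot_event` links).
#' @export
simulate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  grid <- cfg$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  px_ha <- pixel_area_ha(grid)
  months <- cfg$months
  n_months <- length(months)
  sp <- class_spectra()
  bands <- band_set()

  # --- place burn events (connected, mutually disjoint) ----------------------
  event_id <- matrix(0L, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  events <- NULL
  if (cfg$n_burn_events > 0) {
    if (is.null(cfg$burn_month_assignment)) {
      # prefer months with a full 3-month pre-fire window inside the run
      eligible <- if (n_months > 3) months[-(1:3)] else months
      burn_months <- eligible[sample.int(length(eligible), cfg$n_burn_events,
                                         replace = TRUE)]
    } else burn_months <- cfg$burn_month_assignment
    sizes_ha <- stats::runif(cfg$n_burn_events, cfg$burn_size_range[1],
                             cfg$burn_size_range[2])
    target_px <- pmax(1L, as.integer(round(sizes_ha / px_ha)))
    for (e in seq_len(cfg$n_burn_events)) {
      placed <- FALSE
      for (try in 1:25) {
        fp <- grow_patch(occupied, target_px[e], grid)
        if (!is.null(fp)) {
          event_id[fp] <- e
          occupied[fp] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place burn event %d (%d px) without overlap after 25 tries",
                     e, target_px[e]), call. = FALSE)
    }
    events <- data.frame(event = seq_len(cfg$n_burn_events),
                         month = format(burn_months),
                         n_pixels = tabulate(event_id[event_id > 0],
                                             cfg$n_burn_events))
    events$area_ha <- events$n_pixels * px_ha
  } else {
    events <- data.frame(event = integer(), month = character(),
                         n_pixels = integer(), area_ha = numeric())
  }

  # --- place confusers, kept > jitter distance from any event ----------------
  confuser_id <- matrix(0L, nr, nc)
  sep_px <- as.integer(ceiling(cfg$hotspot_jitter_m / grid$pixel_size)) + 1L
  keep_out <- dilate_by_disc(occupied, min(sep_px, max(nr, nc)))
  confusers <- data.frame(confuser = integer(), onset_month = character(),
                          n_pixels = integer())
  if (cfg$n_confusers > 0) {
    conf_sizes <- pmax(1L, as.integer(round(
      stats::runif(cfg$n_confusers, cfg$burn_size_range[1], cfg$burn_size_range[2]) / px_ha)))
    onset_pool <- if (n_months > 3) months[-(1:3)] else months
    onsets <- onset_pool[sample.int(length(onset_pool), cfg$n_confusers,
                                    replace = TRUE)]
    for (k in seq_len(cfg$n_confusers)) {
      placed <- FALSE
      for (try in 1:25) {
        fp <- grow_patch(keep_out, conf_sizes[k], grid)
        if (!is.null(fp)) {
          confuser_id[fp] <- k
          keep_out[fp] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place confuser %d (%d px) clear of events after 25 tries",
                     k, conf_sizes[k]), call. = FALSE)
    }
    confusers <- data.frame(confuser = seq_len(cfg$n_confusers),
                            onset_month = format(onsets),
                            n_pixels = tabulate(confuser_id[confuser_id > 0],
                                                cfg$n_confusers))
  }

  # --- per-month mean reflectance fields -------------------------------------
  ev_burn_idx <- if (nrow(events)) unclass(as_month(events$month)) else integer()
  conf_onset_idx <- if (nrow(confusers)) unclass(as_month(confusers$onset_month)) else integer()
  month_means <- vector("list", n_months)
  for (mi in seq_len(n_months)) {
    m_idx <- unclass(months)[mi]
    mats <- lapply(bands, function(b) matrix(sp["vegetation", b], nr, nc))
    names(mats) <- bands
    for (e in seq_len(nrow(events))) {
      lag <- m_idx - ev_burn_idx[e]
      if (lag < 0) next
      s <- burn_severity(lag, cfg$regrowth_halflife_months)
      idx <- which(event_id == e)
      for (b in bands)
        mats[[b]][idx] <- sp["vegetation", b] + s * (sp["burned", b] - sp["vegetation", b])
    }
    for (k in seq_len(nrow(confusers))) {
      if (m_idx < conf_onset_idx[k]) next
      idx <- which(confuser_id == k)
      for (b in bands) mats[[b]][idx] <- sp["wet_soil", b]
    }
    month_means[[mi]] <- mats
  }

  # --- observations ----------------------------------------------------------
  obs <- list()
  for (mi in seq_len(n_months)) {
    rng <- month_date_range(months[mi])
    days <- seq(rng[1], rng[2], by = cfg$revisit_days)
    for (d in seq_along(days)) {
      bmats <- lapply(month_means[[mi]], function(mu) {
        v <- mu + stats::rnorm(nr * nc, sd = cfg$noise_sd)
        v[v < 0] <- 0
        matrix(v, nr, nc)
      })
      valid <- matrix(stats::runif(nr * nc) >= cfg$cloud_prob, nr, nc)
      for (b in bands) bmats[[b]][!valid] <- NA_real_
      obs[[length(obs) + 1L]] <- list(date = days[d], bands = bmats, valid = valid)
    }
  }
  stack <- structure(list(grid = grid, band_set = bands, obs = obs),
                     class = "scene_stack")

  # --- hotspots --------------------------------------------------------------
  hs <- list()
  conf_any <- confuser_id > 0
  for (e in seq_len(nrow(events))) {
    if (stats::runif(1) < cfg$hotspot_miss_prob) next
    area_km2 <- events$area_ha[e] / 100
    n_pts <- max(1L, stats::rpois(1, cfg$hotspot_density * area_km2))
    fp <- which(event_id == e)
    rng <- month_date_range(as_month(events$month[e]))
    for (p in seq_len(n_pts)) {
      for (try in 1:50) {
        idx <- fp[sample.int(length(fp), 1L)]
        r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
        ctr <- pixel_centres(grid, r, c)
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- cfg$hotspot_jitter_m * sqrt(stats::runif(1))
        x <- ctr[1] + rad * cos(ang); y <- ctr[2] + rad * sin(ang)
        # construction constraint: never emit a hotspot within jitter
        # distance of a confuser patch
        if (!near_mask(grid, conf_any, x, y, cfg$hotspot_jitter_m)) break
      }
      day <- rng[1] + sample.int(as.integer(rng[2] - rng[1]) + 1L, 1L) - 1L
      hs[[length(hs) + 1L]] <- data.frame(
        date = day, x = x, y = y,
        sensor_resolution_m = cfg$hotspot_jitter_m, event = e)
    }
  }
  hotspots <- if (length(hs)) do.call(rbind, hs) else
    data.frame(date = as.Date(character()), x = numeric(), y = numeric(),
               sensor_resolution_m = numeric(), event = integer())
  truth <- structure(list(grid = grid, event_id = event_id,
                          confuser_id = confuser_id,
                          burn_count = (event_id > 0) + 0L,
                          events = events, confusers = confusers,
                          months = months),
                     class = "truth_set")
  list(stack = stack,
       hotspots = hotspots[, c("date", "x", "y", "sensor_resolution_m")],
       hotspot_event = hotspots$event,
       truth = truth)
}

# TRUE if (x, y) lies within dist_m of the centre of any TRUE cell of mask.
near_mask <- function(grid, mask, x, y, dist_m) {
  if (!any(mask)) return(FALSE)
  rc <- map_to_pixel(grid, x, y)
  rad <- ceiling(dist_m / grid$pixel_size) + 1L
  r0 <- if (is.na(rc[1])) round((grid$origin[2] - y) / grid$pixel_size) else rc[1]
  c0 <- if (is.na(rc[2])) round((x - grid$origin[1]) / grid$pixel_size) else rc[2]
  rows <- max(1L, r0 - rad):min(grid$n_rows, r0 + rad)
  cols <- max(1L, c0 - rad):min(grid$n_cols, c0 + rad)
  sub <- mask[rows, cols, drop = FALSE]
  if (!any(sub)) return(FALSE)
  w <- which(sub, arr.ind = TRUE)
  ctr <- pixel_centres(grid, rows[w[, 1]], cols[w[, 2]])
  any((ctr[, 1] - x)^2 + (ctr[, 2] - y)^2 <= dist_m^2)
}

#' @export
print.scene_stack <- function(x, ...) {
  dates <- as.Date(vapply(x$obs, function(o) as.character(o$date), ""))
  cat(sprintf("<scene_stack> %d observations (%s .. %s), %d bands, grid %s\n",
              length(x$obs), min(dates), max(dates), length(x$band_set),
              format(x$grid)))
  invisible(x)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d burn events (%.1f ha), %d confusers, grid %s\n",
              nrow(x$events), sum(x$events$area_ha), nrow(x$confusers),
              format(x$grid)))
  invisible(x)
}

#' Sample labelled training points from the ground truth
#'
#' Draws `n_burned` pixels from event footprints (label 0, month = the
#' event's burn month) and `n_unburned` pixels from unburned land (label 1).
#' When confuser patches exist, the unburned sample deliberately includes
#' them as hard negatives (month = the patch onset month), mirroring training
#' sets augmented against wet-soil false positives.
#'
#' @param truth a `truth_set` from [simulate_stack()].
#' @param n_burned,n_unburned requested counts per class.
#' @param seed integer seed.
#' @param confuser_frac fraction of the unburned sample drawn from confuser
#'   pixels (subject to availability).
#' @param months months assignable to background (vegetation) points;
#'   defaults to all simulated months.
#' @return data.frame with row, col, x, y, label (0 burned / 1 unburned),
#'   month.
#' @export
sample_training_points <- function(truth, n_burned, n_unburned, seed = 1L,
                                   confuser_frac = 0.2, months = NULL) {
  if (is.null(months)) months <- truth$months
  months <- as_month(months)
  set.seed(seed)
  grid <- truth$grid
  burned_idx <- which(truth$event_id > 0)
  conf_idx <- which(truth$confuser_id > 0)
  bg_idx <- which(truth$event_id == 0 & truth$confuser_id == 0)
  if (n_burned > length(burned_idx))
    stop(sprintf("requested %d burned points but only %d burned pixels exist",
                 n_burned, length(burned_idx)), call. = FALSE)
  n_conf <- min(length(conf_idx), round(confuser_frac * n_unburned))
  if (n_unburned - n_conf > length(bg_idx))
    stop("not enough unburned pixels for the requested sample", call. = FALSE)

  take <- function(pool, n) if (n > 0) pool[sample.int(length(pool), n)] else integer()
  b <- take(burned_idx, n_burned)
  cf <- take(conf_idx, n_conf)
  bg <- take(bg_idx, n_unburned - n_conf)

  mk_df <- function(idx, label, month) {
    if (!length(idx)) return(NULL)
    r <- (idx - 1L) %% grid$n_rows + 1L
    c <- (idx - 1L) %/% grid$n_rows + 1L
    ctr <- pixel_centres(grid, r, c)
    data.frame(row = r, col = c, x = ctr[, 1], y = ctr[, 2],
               label = label, month = month)
  }
  ev_month <- truth$events$month[truth$event_id[b]]
  conf_month <- truth$confusers$onset_month[truth$confuser_id[cf]]
  bg_month <- format(months[sample.int(length(months), length(bg),
                                       replace = TRUE)])
  out <- rbind(mk_df(b, 0L, ev_month), mk_df(cf, 1L, conf_month),
               mk_df(bg, 1L, bg_month))
  rownames(out) <- NULL
  out
}

#' Sample stratified reference points for map validation
#'
#' Strata are the map classes of the supplied burn maps (burned = detected as
#' `burned_new` in any map). Each point records its map class, true class
#' (from the ground truth), stratum, true burn month and detected month, as
#' needed by the accuracy and temporal-confusion estimators.
#'
#' @param maps list of `burn_map` objects (one per month) or a single logical
#'   matrix of mapped burned pixels.
#' @param truth a `truth_set`.
#' @param strata_counts named integer vector `c(burned = ..., unburned = ...)`.
#' @param seed integer seed.
#' @return data.frame with row, col, x, y, stratum, map_class, true_class,
#'   true_burn_month, detected_month.
#' @export
sample_reference_points <- function(maps, truth, strata_counts, seed = 1L) {
  set.seed(seed)
  grid <- truth$grid
  stopifnot(all(c("burned", "unburned") %in% names(strata_counts)))
  if (is.matrix(maps)) {
    mapped <- maps
    detected <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  } else {
    mapped <- matrix(FALSE, grid$n_rows, grid$n_cols)
    detected <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
    for (bm in maps) {
      check_same_grid(bm$grid, grid, "burn map and truth")
      new <- bm$state == BURN_STATE["burned_new"]
      first <- new & !mapped
      detected[first] <- unclass(bm$month)
      mapped <- mapped | new
    }
  }
  observable <- !is.na(mapped)
  pools <- list(burned = which(mapped & observable),
                unburned = which(!mapped & observable))
  out <- NULL
  for (s in c("burned", "unburned")) {
    n <- strata_counts[[s]]
    if (n == 0) next
    if (n > length(pools[[s]]))
      stop(sprintf("stratum '%s' has %d pixels, %d requested", s,
                   length(pools[[s]]), n), call. = FALSE)
    idx <- pools[[s]][sample.int(length(pools[[s]]), n)]
    r <- (idx - 1L) %% grid$n_rows + 1L
    c <- (idx - 1L) %/% grid$n_rows + 1L
    ctr <- pixel_centres(grid, r, c)
    ev <- truth$event_id[idx]
    tb <- ifelse(ev > 0, truth$events$month[ifelse(ev > 0, ev, 1L)], NA)
    dm <- detected[idx]
    out <- rbind(out, data.frame(
      row = r, col = c, x = ctr[, 1], y = ctr[, 2],
      stratum = s, map_class = s,
      true_class = ifelse(ev > 0, "burned", "unburned"),
      true_burn_month = tb,
      detected_month = ifelse(is.na(dm), NA_character_,
                              format(structure(dm, class = "month_key")))))
  }
  rownames(out) <- NULL
  out
}
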