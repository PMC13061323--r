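# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own compiled/vectorised
# implementations.

# Flood-fill connected-component labelling, queue-based, pure R.
oracle_label <- function(mask, connectivity = 8) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      idx <- queue[1]; queue <- queue[-1]
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- c + dc[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) { lab[j] <- nxt; queue <- c(queue, j) }
      }
    }
  }
  lab
}

# Labelling-equivalence check: same partition of foreground pixels, up to
# label renumbering.
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  if (!any(fg)) return(TRUE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Small-patch filter oracle built on oracle_label.
oracle_remove_small <- function(mask, min_pixels, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0], max(lab))
  matrix(lab > 0 & sizes[pmax(lab, 1)] >= min_pixels, nrow(mask), ncol(mask))
}

# Hotspot-masking oracle: for every component, the exhaustive Euclidean
# distance from each in-window hotspot to every burned-pixel centre.
oracle_hotspot_filter <- function(mask, hotspots, grid, ref, buffer_m,
                                  window_months, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0) return(mask & FALSE)
  rng <- month_date_range(month_window(ref, 0, window_months))
  hs <- hotspots[hotspots$date >= rng[1] & hotspots$date <= rng[2], , drop = FALSE]
  keep <- logical(max(lab))
  if (nrow(hs)) {
    w <- which(lab > 0, arr.ind = TRUE)
    ctr <- pixel_centres(grid, w[, 1], w[, 2])
    lv <- lab[lab > 0]
    for (i in seq_len(nrow(hs))) {
      d2 <- (ctr[, 1] - hs$x[i])^2 + (ctr[, 2] - hs$y[i])^2
      keep[unique(lv[d2 <= buffer_m^2])] <- TRUE
    }
  }
  matrix(lab > 0 & keep[pmax(lab, 1)], nrow(mask), ncol(mask))
}

# Chebyshev dilation by radius r (square neighbourhood), plain R.
dilate_by_disc_test <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

# Logical matrix with a filled rectangle of TRUE.
rect_mask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# Minimal scene stack with explicit per-observation band values: `values`
# is a list of lists(date, value, valid) and every band carries the same
# value grid (convenient for median tests).
toy_stack <- function(grid, obs_spec) {
  obs <- lapply(obs_spec, function(o) {
    v <- o$value
    if (is.null(o$valid)) o$valid <- !is.na(v)
    bands <- stats::setNames(rep(list(v), length(band_set())), band_set())
    bands <- lapply(bands, function(b) { b[!o$valid] <- NA_real_; b })
    list(date = as.Date(o$date), bands = bands, valid = o$valid)
  })
  structure(list(grid = grid, band_set = band_set(), obs = obs),
            class = "scene_stack")
}

# A burn_map with a given state matrix.
toy_burn_map <- function(state, month, grid = grid_spec(nrow(state), ncol(state))) {
  structure(list(grid = grid, state = state, month = as_month(month)),
            class = "burn_map")
}

# Small simulated scene reused by several files (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(grid = grid_spec(96, 96), n_burn_events = 2,
                        burn_size_range = c(15, 40), n_confusers = 1,
                        cloud_prob = 0.15, hotspot_jitter_m = 200, seed = 42)
      cache <<- simulate_stack(cfg)
    }
    cache
  }
})
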