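#' Rebalance a stratified reference sample against a second map
#'
#' Validating a monthly product with a sample drawn for an annual product
#' breaks the equal-inclusion-probability requirement of stratified random
#' sampling. This operation fixes the sample per cross-stratum (monthly map
#' class x annual map class): strata above their target are reduced by
#' uniform subsampling, strata below it are topped up with points sampled
#' uniformly from the stratum's pixels. Strata without a target are left
#' untouched.
#'
#' @param points data.frame with at least row, col; map classes are derived
#'   from the two maps.
#' @param monthly_map,annual_map logical matrices of mapped burned pixels on
#'   one grid.
#' @param targets named integer vector; names are cross-strata
#'   `"<monthly>_<annual>"` with classes `burned`/`unburned`, e.g.
#'   `c(unburned_burned = 20, burned_unburned = 4, burned_burned = 150)`.
#' @param truth optional `truth_set` supplying the true class of added
#'   points; required when any stratum must grow.
#' @param grid [grid_spec()] of the maps (needed to give added points
#'   coordinates).
#' @param seed integer seed.
#' @return data.frame like `points` with a `cross_stratum` column.
#' @export
rebalance_sample <- function(points, monthly_map, annual_map, targets,
                             truth = NULL, grid = NULL, seed = 1L) {
  stopifnot(all(dim(monthly_map) == dim(annual_map)))
  set.seed(seed)
  cls <- function(m, r, c) ifelse(m[cbind(r, c)], "burned", "unburned")
  points$cross_stratum <- paste(cls(monthly_map, points$row, points$col),
                                cls(annual_map, points$row, points$col),
                                sep = "_")
  strat_of_pixels <- NULL
  out <- points[!points$cross_stratum %in% names(targets), , drop = FALSE]
  for (s in names(targets)) {
    cur <- points[points$cross_stratum == s, , drop = FALSE]
    tgt <- targets[[s]]
    if (nrow(cur) > tgt) {
      cur <- cur[sample.int(nrow(cur), tgt), , drop = FALSE]
    } else if (nrow(cur) < tgt) {
      if (is.null(truth) || is.null(grid))
        stop("growing stratum '", s, "' requires truth and grid", call. = FALSE)
      parts <- strsplit(s, "_")[[1]]
      pool_mask <- (monthly_map == (parts[1] == "burned")) &
        (annual_map == (parts[2] == "burned"))
      pool <- which(pool_mask)
      pool <- setdiff(pool, (cur$col - 1L) * nrow(monthly_map) + cur$row)
      need <- tgt - nrow(cur)
      if (length(pool) < need)
        stop(sprintf("stratum '%s' has only %d pixels for %d additional points",
                     s, length(pool), need), call. = FALSE)
      idx <- pool[sample.int(length(pool), need)]
      r <- (idx - 1L) %% nrow(monthly_map) + 1L
      c <- (idx - 1L) %/% nrow(monthly_map) + 1L
      ctr <- pixel_centres(grid, r, c)
      add <- data.frame(row = r, col = c, x = ctr[, 1], y = ctr[, 2],
                        stratum = parts[1], map_class = parts[1],
                        true_class = ifelse(truth$event_id[idx] > 0,
                                            "burned", "unburned"),
                        true_burn_month = ifelse(
                          truth$event_id[idx] > 0,
                          truth$events$month[pmax(truth$event_id[idx], 1L)], NA),
                        detected_month = NA_character_,
                        cross_stratum = s)
      common <- intersect(names(cur), names(add))
      cur <- rbind(cur[, common, drop = FALSE], add[, common, drop = FALSE])
      out <- out[, common, drop = FALSE]
    }
    out <- rbind(out, cur)
  }
  rownames(out) <- NULL
  out
}

#' Stratified area-weighted accuracy assessment
#'
#' Good-practice stratified estimators for a burned/unburned map validated
#' with a stratified random reference sample. Strata are the map classes;
#' the error matrix is expressed in area proportions
#' `p_ij = W_i * n_ij / n_i` (i = map class, j = reference class, W_i the
#' stratum's share of the map area). Overall accuracy is the diagonal sum,
#' user's accuracy the within-row and producer's accuracy the within-column
#' diagonal shares. 95% confidence intervals use the normal approximation of
#' the stratified variances.
#'
#' @param points data.frame with `map_class` and `true_class` columns
#'   (values `"burned"`/`"unburned"`).
#' @param strata_pixels named numeric vector of map pixel counts (or areas)
#'   per class, `c(burned = ..., unburned = ...)`.
#' @return object of class `accuracy_report` with the count and proportion
#'   matrices and OA/UA/PA (percent) with CI bounds.
#' @export
accuracy_assessment <- function(points, strata_pixels) {
  classes <- c("burned", "unburned")
  stopifnot(all(points$map_class %in% classes),
            all(points$true_class %in% classes),
            all(classes %in% names(strata_pixels)))
  n <- table(factor(points$map_class, classes), factor(points$true_class, classes))
  n <- unclass(n)
  ni <- rowSums(n)
  if (any(ni == 0 & strata_pixels[classes] > 0))
    stop("a stratum with nonzero area has no sample points", call. = FALSE)
  W <- strata_pixels[classes] / sum(strata_pixels[classes])
  p <- matrix(0, 2, 2, dimnames = dimnames(n))
  for (i in 1:2) if (ni[i] > 0) p[i, ] <- W[i] * n[i, ] / ni[i]

  oa <- sum(diag(p))
  ua <- ifelse(ni > 0, diag(n) / ni, NA_real_)
  pj <- colSums(p)
  pa <- ifelse(pj > 0, diag(p) / pj, NA_real_)

  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  v_ua <- safe_div(ua * (1 - ua), ni - 1)
  v_oa <- sum(W^2 * v_ua, na.rm = TRUE)
  # producer's accuracy variance, stratified (estimated reference-class areas)
  Npix <- strata_pixels[classes]
  v_pa <- numeric(2)
  for (j in 1:2) {
    Nj_hat <- sum(safe_div(Npix * n[, j], ni))
    if (Nj_hat == 0) { v_pa[j] <- NA_real_; next }
    i_not <- setdiff(1:2, j)
    term1 <- Npix[j]^2 * (1 - pa[j])^2 * ua[j] * (1 - ua[j]) /
      max(ni[j] - 1, 1)
    term2 <- pa[j]^2 * sum(Npix[i_not]^2 *
                             safe_div(n[i_not, j], ni[i_not]) *
                             (1 - safe_div(n[i_not, j], ni[i_not])) /
                             pmax(ni[i_not] - 1, 1))
    v_pa[j] <- (term1 + term2) / Nj_hat^2
  }
  z <- stats::qnorm(0.975)
  pct <- function(est, v) {
    se <- sqrt(pmax(v, 0))
    cbind(estimate = 100 * est,
          lo = pmax(0, 100 * (est - z * se)),
          hi = pmin(100, 100 * (est + z * se)))
  }
  structure(list(counts = n, proportions = p, weights = W,
                 oa = pct(oa, v_oa)[1, ],
                 ua = {m <- pct(ua, v_ua); rownames(m) <- classes; m},
                 pa = {m <- pct(pa, v_pa); rownames(m) <- classes; m},
                 n_points = nrow(points)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d reference points\n", x$n_points))
  cat(sprintf("  OA: %.1f%% (%.1f, %.1f)\n", x$oa["estimate"], x$oa["lo"], x$oa["hi"]))
  for (cl in rownames(x$ua))
    cat(sprintf("  UA %-8s: %5.1f%% (%.1f, %.1f)   PA %-8s: %5.1f%% (%.1f, %.1f)\n",
                cl, x$ua[cl, "estimate"], x$ua[cl, "lo"], x$ua[cl, "hi"],
                cl, x$pa[cl, "estimate"], x$pa[cl, "lo"], x$pa[cl, "hi"]))
  cat(sprintf("  commission (burned): %.1f%%   omission (burned): %.1f%%\n",
              commission_error(x$ua["burned", "estimate"]),
              omission_error(x$pa["burned", "estimate"])))
  invisible(x)
}

#' Commission and omission error rates
#'
#' By definition the commission error of a class is 100 minus its user's
#' accuracy, and the omission error is 100 minus its producer's accuracy
#' (percentage scale).
#'
#' @param ua,pa user's / producer's accuracy in percent.
#' @return error rate in percent.
#' @export
commission_error <- function(ua) 100 - ua

#' @rdname commission_error
#' @export
omission_error <- function(pa) 100 - pa

#' Temporal confusion between detected and true burn months
#'
#' Cross-tabulates the month assigned by the processing chain against the
#' reference burn month, and reports the exact-month agreement rate and the
#' rate of mismatches of more than one month. Points lacking either month
#' are excluded.
#'
#' @param points data.frame with `detected_month` and `true_burn_month`
#'   columns (`"YYYY-MM"` strings).
#' @return list with `matrix` (detected x true counts), `n`, `agreement`
#'   (exact-month fraction), `gt1_month` (fraction off by more than one
#'   month).
#' @export
temporal_confusion <- function(points) {
  ok <- !is.na(points$detected_month) & !is.na(points$true_burn_month)
  d <- unclass(as_month(points$detected_month[ok]))
  t <- unclass(as_month(points$true_burn_month[ok]))
  if (!length(d))
    return(list(matrix = table(character(), character()), n = 0L,
                agreement = NA_real_, gt1_month = NA_real_))
  lv <- format(structure(seq(min(c(d, t)), max(c(d, t))), class = "month_key"))
  mat <- table(detected = factor(format(structure(d, class = "month_key")), lv),
               true = factor(format(structure(t, class = "month_key")), lv))
  list(matrix = mat, n = length(d),
       agreement = mean(d == t),
       gt1_month = mean(abs(d - t) > 1))
}

#' Burned-patch size distribution
#'
#' Connected-component areas (hectares) of the newly burned pixels of one or
#' several monthly maps.
#'
#' @param maps a `burn_map`, a list of them, or a logical matrix (then `grid`
#'   must be given).
#' @param connectivity patch connectivity (default 8, matching the pipeline).
#' @param grid required when `maps` is a bare matrix.
#' @return numeric vector of patch areas in hectares (class
#'   `size_distribution`).
#' @export
patch_sizes <- function(maps, connectivity = 8, grid = NULL) {
  if (inherits(maps, "burn_map")) maps <- list(maps)
  if (is.matrix(maps)) {
    stopifnot(!is.null(grid))
    maps <- list(list(grid = grid, state = ifelse(maps, 1L, 0L)))
  }
  sizes <- numeric()
  for (bm in maps) {
    px <- pixel_area_ha(bm$grid)
    lab <- label_patches(bm$state == BURN_STATE[["burned_new"]], connectivity)
    if (max(lab) > 0)
      sizes <- c(sizes, tabulate(lab[lab > 0L], max(lab)) * px)
  }
  structure(sizes, class = "size_distribution")
}

#' Compare two burn-size distributions above size thresholds
#'
#' For each threshold, patches at least that large are compared with the
#' Kruskal-Wallis H test, the two-sample Kolmogorov-Smirnov test and the
#' Mann-Whitney U (Wilcoxon rank-sum) test. Rows where either sample is
#' empty are marked not applicable (NA).
#'
#' @param dist_a,dist_b numeric vectors of patch areas (ha).
#' @param thresholds size thresholds in hectares.
#' @return data.frame with one row per threshold: sample sizes, statistics
#'   and p-values.
#' @export
size_distribution_tests <- function(dist_a, dist_b,
                                    thresholds = c(25, 100, 1000, 5000)) {
  res <- lapply(thresholds, function(thr) {
    a <- dist_a[dist_a >= thr]; b <- dist_b[dist_b >= thr]
    if (!length(a) || !length(b))
      return(data.frame(threshold_ha = thr, n_a = length(a), n_b = length(b),
                        kw_stat = NA_real_, kw_p = NA_real_,
                        ks_stat = NA_real_, ks_p = NA_real_,
                        mw_stat = NA_real_, mw_p = NA_real_))
    kw <- stats::kruskal.test(list(a, b))
    ks <- suppressWarnings(stats::ks.test(a, b))
    mw <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(threshold_ha = thr, n_a = length(a), n_b = length(b),
               kw_stat = unname(kw$statistic), kw_p = kw$p.value,
               ks_stat = unname(ks$statistic), ks_p = ks$p.value,
               mw_stat = unname(mw$statistic), mw_p = mw$p.value)
  })
  do.call(rbind, res)
}

#' Cumulative burned area as a function of patch size
#'
#' @param dist numeric vector of patch areas (ha).
#' @return data.frame with `size_ha` (ascending) and `cumulative_ha`
#'   (non-decreasing; terminal value is the total area).
#' @export
cumulative_curve <- function(dist) {
  stopifnot(length(dist) > 0, all(dist > 0))
  s <- sort(as.numeric(dist))
  data.frame(size_ha = s, cumulative_ha = cumsum(s))
}
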