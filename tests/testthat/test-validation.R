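test_that("stratified estimates match a hand-computed 2x2 error matrix", {
  # counts (map x true): burned 45/5, unburned 10/40; equal strata areas
  pts <- data.frame(
    map_class = rep(c("burned", "unburned"), times = c(50, 50)),
    true_class = c(rep("burned", 45), rep("unburned", 5),
                   rep("burned", 10), rep("unburned", 40)))
  rep_ <- accuracy_assessment(pts, c(burned = 1000, unburned = 1000))
  # hand computation: W = (.5, .5); p = W_i * n_ij / n_i
  # p = [.45 .05; .10 .40]; OA = .85; UA_b = .90; PA_b = .45/.55
  expect_equal(unname(rep_$oa["estimate"]), 85)
  expect_equal(unname(rep_$ua["burned", "estimate"]), 90)
  expect_equal(unname(rep_$ua["unburned", "estimate"]), 80)
  expect_equal(unname(rep_$pa["burned", "estimate"]), 100 * 0.45 / 0.55)
  expect_equal(unname(rep_$pa["unburned", "estimate"]), 100 * 0.40 / 0.45)
  expect_equal(sum(rep_$proportions), 1)
  # hand variance of UA_burned: p(1-p)/(n-1) = .9*.1/49
  se <- sqrt(0.9 * 0.1 / 49)
  expect_equal(unname(rep_$ua["burned", "hi"] - rep_$ua["burned", "lo"]),
               2 * stats::qnorm(0.975) * se * 100, tolerance = 1e-10)
  # commission/omission identities
  expect_equal(commission_error(rep_$ua["burned", "estimate"]),
               100 - rep_$ua["burned", "estimate"])
  expect_equal(omission_error(rep_$pa["burned", "estimate"]),
               100 - rep_$pa["burned", "estimate"])
})

test_that("perfect agreement gives 100% accuracies with zero-width CIs", {
  pts <- data.frame(map_class = rep(c("burned", "unburned"), c(30, 70)),
                    true_class = rep(c("burned", "unburned"), c(30, 70)))
  rep_ <- accuracy_assessment(pts, c(burned = 200, unburned = 800))
  expect_equal(unname(rep_$oa["estimate"]), 100)
  expect_equal(unname(rep_$ua[, "estimate"]), c(100, 100))
  expect_equal(unname(rep_$pa[, "estimate"]), c(100, 100))
  expect_equal(unname(rep_$oa["hi"] - rep_$oa["lo"]), 0)
  expect_error(accuracy_assessment(pts[pts$map_class == "burned", ],
                                   c(burned = 200, unburned = 800)),
               "no sample points")
})

test_that("estimates fall within CI of exhaustively computed map accuracy", {
  sim <- small_sim()
  truth_burn <- sim$truth$event_id > 0
  # an imperfect map: scars eroded by one pixel, plus a false patch
  mapped <- truth_burn & !dilate_by_disc_test(!truth_burn, 1)
  mapped[1:6, 90:96] <- TRUE
  pts <- sample_reference_points(mapped, sim$truth,
                                 c(burned = 80, unburned = 200), seed = 31)
  rep_ <- accuracy_assessment(pts, c(burned = sum(mapped),
                                     unburned = sum(!mapped)))
  ua_true <- 100 * sum(mapped & truth_burn) / sum(mapped)
  pa_true <- 100 * sum(mapped & truth_burn) / sum(truth_burn)
  expect_gte(ua_true, rep_$ua["burned", "lo"])
  expect_lte(ua_true, rep_$ua["burned", "hi"])
  expect_gte(pa_true, rep_$pa["burned", "lo"])
  expect_lte(pa_true, rep_$pa["burned", "hi"])
})

test_that("rebalancing hits its cross-stratum targets deterministically", {
  sim <- small_sim()
  g <- sim$truth$grid
  monthly <- sim$truth$event_id > 0
  annual <- dilate_by_disc_test(monthly, 2)   # annual map detects more
  pts <- sample_reference_points(monthly, sim$truth,
                                 c(burned = 60, unburned = 300), seed = 12)
  targets <- c(unburned_burned = 20, burned_burned = 40)
  out <- rebalance_sample(pts, monthly, annual, targets,
                          truth = sim$truth, grid = g, seed = 3)
  got <- table(out$cross_stratum)
  expect_equal(unname(got[["unburned_burned"]]), 20)
  expect_equal(unname(got[["burned_burned"]]), 40)
  # untouched strata keep their original counts
  orig <- paste(ifelse(monthly[cbind(pts$row, pts$col)], "burned", "unburned"),
                ifelse(annual[cbind(pts$row, pts$col)], "burned", "unburned"),
                sep = "_")
  expect_equal(sum(out$cross_stratum == "unburned_unburned"),
               sum(orig == "unburned_unburned"))
  # identity when targets equal current counts
  cur <- table(orig)
  same <- rebalance_sample(pts, monthly, annual,
                           c(burned_burned = unname(cur[["burned_burned"]])),
                           seed = 3)
  expect_equal(nrow(same), nrow(pts))
  # determinism
  out2 <- rebalance_sample(pts, monthly, annual, targets,
                           truth = sim$truth, grid = g, seed = 3)
  expect_identical(out, out2)
})

test_that("rebalancing supports add, reduce-to-4 and reduce-to-150 targets at once", {
  sim <- small_sim()
  g <- sim$truth$grid
  set.seed(19)
  # independent monthly and annual maps so all four cross-strata are populated
  monthly <- matrix(runif(g$n_rows * g$n_cols) < 0.3, g$n_rows, g$n_cols)
  annual <- matrix(runif(g$n_rows * g$n_cols) < 0.3, g$n_rows, g$n_cols)
  pts <- sample_reference_points(monthly, sim$truth,
                                 c(burned = 300, unburned = 600), seed = 23)
  out <- rebalance_sample(pts, monthly, annual,
                          c(unburned_burned = 20, burned_unburned = 4,
                            burned_burned = 150),
                          truth = sim$truth, grid = g, seed = 9)
  got <- table(out$cross_stratum)
  expect_equal(unname(got[["unburned_burned"]]), 20)
  expect_equal(unname(got[["burned_unburned"]]), 4)
  expect_equal(unname(got[["burned_burned"]]), 150)
})

test_that("temporal confusion counts exact and >1-month mismatches", {
  # 10 points: 7 exact, 2 one-month lags, 1 two-month lag
  tm <- rep("2019-09", 10)
  dm <- c(rep("2019-09", 7), "2019-10", "2019-08", "2019-11")
  tc <- temporal_confusion(data.frame(true_burn_month = tm, detected_month = dm))
  expect_equal(tc$n, 10L)
  expect_equal(tc$agreement, 0.7)
  expect_equal(tc$gt1_month, 0.1)
  expect_equal(sum(tc$matrix), 10)
  # all exact -> diagonal matrix, agreement 1
  tc2 <- temporal_confusion(data.frame(true_burn_month = tm, detected_month = tm))
  expect_equal(tc2$agreement, 1)
  expect_equal(tc2$gt1_month, 0)
  expect_true(all(tc2$matrix[row(tc2$matrix) != col(tc2$matrix)] == 0))
})

test_that("patch sizes convert component pixel counts to hectares", {
  g <- grid_spec(60, 60, 20)
  st <- matrix(BURN_STATE[["unburned"]], 60, 60)
  st[1:13, 1:12] <- BURN_STATE[["burned_new"]]    # 156 px = 6.24 ha
  st[30:49, 30:49] <- BURN_STATE[["burned_new"]]  # 400 px = 16 ha
  bm <- toy_burn_map(st, "2019-06", g)
  expect_equal(sort(as.numeric(patch_sizes(bm))), c(6.24, 16.0))
  # empty map -> empty distribution
  expect_length(patch_sizes(toy_burn_map(matrix(BURN_STATE[["unburned"]], 5, 5),
                                         "2019-06", grid_spec(5, 5, 20))), 0)
  # merged maps vs per-month maps on non-overlapping events agree
  st_a <- matrix(BURN_STATE[["unburned"]], 60, 60)
  st_a[1:13, 1:12] <- BURN_STATE[["burned_new"]]
  st_b <- matrix(BURN_STATE[["unburned"]], 60, 60)
  st_b[30:49, 30:49] <- BURN_STATE[["burned_new"]]
  two <- list(toy_burn_map(st_a, "2019-06", g), toy_burn_map(st_b, "2019-07", g))
  expect_equal(sort(as.numeric(patch_sizes(two))),
               sort(as.numeric(patch_sizes(bm))))
})

test_that("size-distribution tests behave under null, identity and shift", {
  # identical samples: KS statistic exactly 0
  a <- c(30, 50, 200, 1500, 7000)
  t0 <- size_distribution_tests(a, a, thresholds = 25)
  expect_equal(t0$ks_stat, 0)
  # empty side above a threshold -> NA row
  t1 <- size_distribution_tests(c(30, 40), c(30, 60), thresholds = c(25, 5000))
  expect_true(is.na(t1$kw_p[2]))
  expect_false(is.na(t1$kw_p[1]))
  # null calibration: two samples from one lognormal, rejection ~ 5%
  set.seed(71)
  rej <- replicate(200, {
    x <- rlnorm(60, 3, 1); y <- rlnorm(60, 3, 1)
    size_distribution_tests(x, y, thresholds = 0)$kw_p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
  # monotonicity: p drops as the shift grows
  set.seed(72)
  x <- rlnorm(150, 3, 0.8)
  ps <- vapply(c(1, 1.6, 2.6), function(s)
    size_distribution_tests(x, x * s, thresholds = 0)$kw_p, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("cumulative size curves are sorted, monotone and total-preserving", {
  expect_equal(cumulative_curve(c(2, 1, 3))$cumulative_ha, c(1, 3, 6))
  set.seed(4)
  d <- rlnorm(300, 2, 1)
  cc <- cumulative_curve(d)
  expect_true(!is.unsorted(cc$size_ha))
  expect_true(all(diff(cc$cumulative_ha) >= 0))
  expect_equal(cc$cumulative_ha[300], sum(d))
  # power-law sample: tail of the cumulative curve near-linear in log size
  set.seed(5)
  alpha <- 1.6
  pl <- (runif(4000))^(-1 / (alpha - 1))   # Pareto, xmin = 1
  cc <- cumulative_curve(pl)
  # recover the exponent from the upper tail via a log-log regression of the
  # survival function, the standard diagnostic for scale-free patch sizes
  s <- sort(pl)
  surv <- 1 - seq_along(s) / length(s)
  keep <- s > quantile(s, 0.5) & surv > 0
  fit <- stats::lm(log(surv[keep]) ~ log(s[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -(alpha - 1), tolerance = 0.12)
})

test_that("stratified estimators are unbiased with nominal CI coverage", {
  # fixed synthetic map vs truth with known error structure
  set.seed(88)
  nr <- 200; nc <- 200
  truth <- matrix(runif(nr * nc) < 0.3, nr, nc)
  flip <- matrix(runif(nr * nc), nr, nc)
  mapped <- ifelse(truth, flip > 0.15, flip < 0.05)  # UA/PA away from 0/1
  strata <- c(burned = sum(mapped), unburned = sum(!mapped))
  ua_true <- 100 * sum(mapped & truth) / sum(mapped)
  oa_true <- 100 * mean(mapped == truth)
  pa_true <- 100 * sum(mapped & truth) / sum(truth)
  idx_b <- which(mapped); idx_u <- which(!mapped)
  n_b <- 120; n_u <- 220
  draws <- replicate(500, {
    sb <- idx_b[sample.int(length(idx_b), n_b)]
    su <- idx_u[sample.int(length(idx_u), n_u)]
    pts <- data.frame(
      map_class = rep(c("burned", "unburned"), c(n_b, n_u)),
      true_class = ifelse(truth[c(sb, su)], "burned", "unburned"))
    r <- accuracy_assessment(pts, strata)
    c(oa = unname(r$oa["estimate"]),
      oa_cov = oa_true >= r$oa["lo"] && oa_true <= r$oa["hi"],
      ua = unname(r$ua["burned", "estimate"]),
      ua_cov = ua_true >= r$ua["burned", "lo"] && ua_true <= r$ua["burned", "hi"],
      pa = unname(r$pa["burned", "estimate"]),
      pa_cov = pa_true >= r$pa["burned", "lo"] && pa_true <= r$pa["burned", "hi"])
  })
  mc_se <- function(v) stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(draws["oa", ]) - oa_true), 4 * mc_se(draws["oa", ]) + 0.05)
  expect_lt(abs(mean(draws["ua", ]) - ua_true), 4 * mc_se(draws["ua", ]) + 0.05)
  expect_lt(abs(mean(draws["pa", ]) - pa_true), 4 * mc_se(draws["pa", ]) + 0.3)
  for (m in c("oa_cov", "ua_cov", "pa_cov"))
    expect_gte(mean(draws[m, ]), 0.92)
})
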