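## analytic editing profile (percent = 100 * generative probability);
## exercises the aggregation/calling logic without sequencing noise
analytic_profile <- function(construct, profile, arm = "upper") {
  a <- arm_adenosines(construct, arm)
  p <- editing_probability(construct, profile, a, arm = arm)
  out <- data.frame(position = a, a = NA_integer_, g = NA_integer_, percent = 100 * p)
  attr(out, "construct") <- construct$id
  attr(out, "arm") <- arm
  class(out) <- c("editing_profile", "data.frame")
  out
}

test_that("delta profiles subtract the reference and apply the 1% filter", {
  ref <- data.frame(position = c(0, 5, 9), percent = c(50, 0.5, 30))
  var1 <- data.frame(position = c(0, 5, 9), percent = c(65, 10, 30))
  d <- delta_profile(var1, ref)
  expect_equal(d$delta, c(15, 9.5, 0))
  expect_equal(d$excluded, c(FALSE, TRUE, FALSE))

  d0 <- delta_profile(ref, ref)
  expect_true(all(d0$delta == 0))

  expect_error(
    delta_profile(data.frame(position = 100, percent = 1), ref),
    "share no"
  )
})

test_that("distances center each adenosine on its construct's disruption", {
  bb <- small_backbone(stem = 80L)
  prof <- plain_profile(baseline = 0.3)
  ## 3-nt mismatch centered at register 66 (starts at 65)
  con <- new_construct(
    bb, list(perturbation("mismatch", position = 65L, length = 3L)),
    id = "mm66"
  )
  ref <- reference_construct(bb)
  d <- delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
  agg <- aggregate_by_distance(list(mm66 = d), c(list(con), list(ref)))
  a_pos <- con$a_pos_upper
  expect_setequal(agg$points$distance, a_pos - 66L)
  if (40 %in% a_pos) {
    expect_true(-26 %in% agg$points$distance)
  }

  ## multiple perturbations refuse pooling
  con2 <- new_construct(bb, list(
    perturbation("mismatch", position = 10L, length = 1L),
    perturbation("mismatch", position = 40L, length = 1L)
  ), id = "double")
  d2 <- delta_profile(analytic_profile(con2, prof), analytic_profile(ref, prof))
  expect_error(
    aggregate_by_distance(list(double = d2), list(con2, ref)),
    "exactly one"
  )
})

test_that("per-distance quartiles summarize the pooled points", {
  pts <- data.frame(
    construct = c("a", "b"), distance = c(-26, -26),
    delta = c(5, 7)
  )
  agg <- structure(
    list(points = pts, by_distance = NULL, arm = "upper"),
    class = "offset_aggregate"
  )
  ## recompute via the public constructor path
  bb <- small_backbone(stem = 40L)
  prof <- plain_profile()
  ref <- reference_construct(bb)
  cons <- generate_series(bb, "mismatch", size = 1)[c(30, 35)]
  deltas <- lapply(cons, function(con) {
    delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
  })
  names(deltas) <- vapply(cons, `[[`, character(1), "id")
  agg2 <- aggregate_by_distance(deltas, c(cons, list(ref)))
  for (dd in unique(agg2$points$distance)) {
    v <- agg2$points$delta[agg2$points$distance == dd]
    row <- agg2$by_distance[agg2$by_distance$distance == dd, ]
    expect_equal(row$q25, unname(quantile(v, 0.25)))
    expect_equal(row$q75, unname(quantile(v, 0.75)))
    expect_equal(row$n, length(v))
  }
})

test_that("pooling is invariant to construct order and deltas stay bounded", {
  bb <- small_backbone(stem = 60L)
  prof <- plain_profile(baseline = 0.5, fold = 1.8)
  ref <- reference_construct(bb)
  cons <- generate_series(bb, "mismatch", size = 3)
  deltas <- lapply(cons, function(con) {
    delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
  })
  names(deltas) <- vapply(cons, `[[`, character(1), "id")
  lib <- c(cons, list(ref))
  agg_fwd <- aggregate_by_distance(deltas, lib)
  agg_rev <- aggregate_by_distance(rev(deltas), lib)
  expect_equal(agg_fwd$by_distance, agg_rev$by_distance)
  expect_true(all(abs(agg_fwd$points$delta) <= 100))
})

test_that("LOESS smoothing is exact on constants and linear data", {
  x <- seq(-50, 50, length.out = 60)
  sm_const <- loess_smooth(x, rep(3, 60), span = 0.3)
  expect_equal(sm_const$fitted, rep(3, 60), tolerance = 1e-8)

  sm_lin <- loess_smooth(x, 2 * x, span = 0.5)
  interior <- sm_lin$x > -40 & sm_lin$x < 40
  expect_equal(sm_lin$fitted[interior], 2 * sm_lin$x[interior], tolerance = 1e-6)

  expect_error(loess_smooth(x[1:5], x[1:5], 0.5), "at least 10")
  expect_error(loess_smooth(x, 2 * x, 0), "span")
  expect_error(loess_smooth(x, 2 * x, 1.5), "span")
})

test_that("LOESS locates a noisy bump where a longhand local regression does", {
  set.seed(7)
  x <- rep(-70:10, each = 13)
  y <- 12 * exp(-(x + 26)^2 / 8) + rnorm(length(x), 0, 1.5)
  sm <- loess_smooth(x, y, span = 0.05)
  expect_lte(abs(sm$x[which.max(sm$fitted)] - (-26)), 1)
  oracle_fit <- oracle_loess(x, y, span = 0.05)
  xs <- sort(unique(x))
  expect_lte(abs(xs[which.max(oracle_fit)] - (-26)), 1)
  ## implementation and oracle agree closely away from the edges
  interior <- xs > -65 & xs < 5
  expect_lt(max(abs(sm$fitted[interior] - oracle_fit[interior])), 0.8)
})

test_that("extremum calling respects windows, ties and the null flag", {
  fake_agg <- function(fitted_at) {
    structure(
      list(
        points = data.frame(
          construct = "x",
          distance = fitted_at$distance,
          delta = fitted_at$fitted
        ),
        by_distance = NULL,
        smoothed = fitted_at, arm = "upper"
      ),
      class = "offset_aggregate"
    )
  }
  dgrid <- -50:20
  ## single maximum at -26, minimum at 0
  f <- -3 * exp(-(dgrid)^2 / 6) + 5 * exp(-(dgrid + 26)^2 / 4)
  call <- detect_offset_extrema(fake_agg(data.frame(distance = dgrid, fitted = f)))
  expect_equal(call$peak_distance, -26)
  expect_equal(call$trough_distance, 0)
  expect_false(call$no_induction)

  ## exact tie at -27 and -25 resolves toward the smaller |distance|
  f2 <- rep(0, length(dgrid))
  f2[dgrid %in% c(-27, -25)] <- 4
  f2[dgrid == 0] <- -2
  call2 <- detect_offset_extrema(fake_agg(data.frame(distance = dgrid, fitted = f2)))
  expect_equal(call2$peak_distance, -25)

  ## flat zero curve -> no induction
  call3 <- detect_offset_extrema(fake_agg(data.frame(distance = dgrid, fitted = rep(0, length(dgrid)))))
  expect_true(call3$no_induction)
  expect_true(is.na(call3$peak_distance))

  ## negative region surrounds the trough
  expect_true(call$negative_region[1] <= call$trough_distance)
  expect_true(call$negative_region[2] >= call$trough_distance)

  expect_error(
    detect_offset_extrema(
      fake_agg(data.frame(distance = -20:20, fitted = rep(1, 41)))
    ),
    "window outside"
  )
})

test_that("mismatch-size effect ranks sizes by their induction strength", {
  bb <- small_backbone(stem = 80L)
  ref <- reference_construct(bb)
  folds <- c(`1` = 1.2, `2` = 1.5, `3` = 1.9)
  aggs <- lapply(names(folds), function(k) {
    prof <- plain_profile(baseline = 0.4, fold = folds[[k]])
    cons <- generate_series(bb, "mismatch", size = as.integer(k))
    deltas <- lapply(cons, function(con) {
      delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
    })
    names(deltas) <- vapply(cons, `[[`, character(1), "id")
    aggregate_by_distance(deltas, c(cons, list(ref)))
  })
  names(aggs) <- names(folds)
  eff <- mismatch_size_effect(aggs, at_distance = -26)
  expect_equal(eff$size, 1:3)
  expect_true(all(diff(eff$median) > 0))

  ## null profile: medians ~ 0 for all sizes
  aggs0 <- lapply(1:3, function(k) {
    prof <- plain_profile(baseline = 0.4, fold = 1, suppression = flat_suppression())
    cons <- generate_series(bb, "mismatch", size = k)
    deltas <- lapply(cons, function(con) {
      delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
    })
    names(deltas) <- vapply(cons, `[[`, character(1), "id")
    aggregate_by_distance(deltas, c(cons, list(ref)))
  })
  names(aggs0) <- 1:3
  eff0 <- mismatch_size_effect(aggs0, at_distance = -26)
  expect_true(all(abs(eff0$median) < 1e-9))

  expect_error(mismatch_size_effect(aggs[1:2], at_distance = -1000), "absent")
  expect_error(mismatch_size_effect(unname(aggs), at_distance = -26), "named")
})

test_that("context summary recovers the -1 G penalty and the null is flat", {
  bb <- small_backbone(stem = 146L, seed = 3L)
  ref <- reference_construct(bb)
  prof_ctx <- enzyme_profile("ctx",
    baseline_edit_prob = 0.5,
    induction_fold = 1.4,
    context_multipliers = default_context() * 0 +
      outer(c(A = 1, C = 1, G = 0.2, T = 1), c(A = 1, C = 1, G = 1, T = 1))
  )
  profs <- list(perfect = analytic_profile(ref, prof_ctx))
  cs <- sequence_context_summary(profs, list(ref))
  med <- setNames(cs$by_minus1$median, cs$by_minus1$base)
  others <- med[setdiff(names(med), "G")]
  expect_lt(med[["G"]], 0.3 * min(others))
  expect_equal(unname(med[["G"]] / others[[1]]), 0.2, tolerance = 0.01)

  prof_flat <- plain_profile(baseline = 0.5)
  cs0 <- sequence_context_summary(list(perfect = analytic_profile(ref, prof_flat)), list(ref))
  expect_true(all(abs(cs0$by_minus1$median - 50) < 1e-9))
  expect_true(all(abs(cs0$by_plus1$median - 50) < 1e-9))
})

test_that("opposite-base C series induces editing at the substituted position", {
  bb <- small_backbone(stem = 60L)
  ref <- reference_construct(bb)
  prof <- plain_profile(baseline = 0.4)
  cons <- generate_series(bb, "opposite_base", base = "C")
  deltas <- lapply(cons, function(con) {
    delta_profile(analytic_profile(con, prof), analytic_profile(ref, prof))
  })
  names(deltas) <- vapply(cons, `[[`, character(1), "id")
  agg <- aggregate_by_distance(deltas, c(cons, list(ref)))
  at0 <- agg$points$delta[agg$points$distance == 0]
  expect_true(all(at0 > 0)) # A-C mismatch boosts the substituted adenosine
})

test_that("min-max scaling and row z-scoring behave as documented", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(normalize_minmax(c(1, 1, 1)), "degenerate")

  d1 <- data.frame(position = 0:2, delta = c(1, 1, 1))
  d2 <- data.frame(position = 0:2, delta = c(0, 2, 4))
  z <- delta_zmatrix(list(flat = d1, rising = d2))
  expect_identical(attr(z, "constant_rows"), "flat")
  expect_true(all(is.na(z["flat", ])))
  expect_false(any(is.nan(z)))
  expect_equal(unname(z["rising", ]), c(-1, 0, 1))
  expect_equal(unname(attr(z, "raw")["rising", ]), c(0, 2, 4))
})
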