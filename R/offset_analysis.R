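#' Delta editing versus the perfect duplex
#'
#' Per-adenosine difference in editing percent between a structurally
#' perturbed construct and the perfect-duplex reference. Positions whose
#' reference editing is at or below `min_reference_percent` (default 1%)
#' are flagged `excluded` and left out of offset pooling.
#'
#' @param variant,reference `editing_profile` data.frames.
#' @param min_reference_percent Reference-editing inclusion threshold (%).
#' @return A `delta_profile` data.frame with columns `position`, `delta`,
#'   `reference_percent`, `excluded`.
#' @export
delta_profile <- function(variant, reference, min_reference_percent = 1.0) {
  m <- merge(variant[, c("position", "percent")],
    reference[, c("position", "percent")],
    by = "position", suffixes = c("_var", "_ref")
  )
  if (!nrow(m)) stop("variant and reference share no adenosine positions")
  out <- data.frame(
    position = m$position,
    delta = m$percent_var - m$percent_ref,
    reference_percent = m$percent_ref,
    excluded = is.na(m$percent_ref) | is.na(m$percent_var) |
      m$percent_ref <= min_reference_percent
  )
  attr(out, "construct") <- attr(variant, "construct")
  attr(out, "arm") <- attr(variant, "arm")
  class(out) <- c("delta_profile", "data.frame")
  out
}

#' Pool delta editing by signed distance to the disruption
#'
#' Centers each construct's adenosines on its single sliding perturbation
#' (distance = adenosine register minus disruption center register, on the
#' quantified strand; negative = adenosine 5' of the disruption) and pools
#' the (distance, delta) points across the series, with per-distance
#' 25th/75th percentiles.
#'
#' @param deltas Named list of `delta_profile`s (names or attrs give the
#'   construct ids).
#' @param library List of `adar_construct`.
#' @param arm Strand on which the profiles were measured.
#' @param minus1 Optional -1-base filter (e.g. `"G"` to restrict pooling to
#'   GA-context adenosines).
#' @return An `offset_aggregate`: list with `points` (distance, delta,
#'   construct), `by_distance` (distance, n, mean, q25, q75) and `arm`.
#' @export
aggregate_by_distance <- function(deltas, library,
                                  arm = c("upper", "lower"),
                                  minus1 = NULL) {
  arm <- match.arg(arm)
  pts <- vector("list", length(deltas))
  ids <- names(deltas)
  for (i in seq_along(deltas)) {
    d <- deltas[[i]]
    id <- if (!is.null(ids) && nzchar(ids[i])) ids[i] else attr(d, "construct")
    con <- get_construct(library, id)
    active <- Filter(function(p) p$kind != "none", con$perturbations)
    if (length(active) != 1L) {
      stop(
        "construct ", id, " carries ", length(active),
        " perturbations; sliding-series pooling needs exactly one"
      )
    }
    if (active[[1]]$kind == "random_disruption") {
      stop(
        "construct ", id,
        " is a random-disruption variant with no single center"
      )
    }
    centers <- disruption_centers(con, arm)
    keep <- !d$excluded
    if (!is.null(minus1)) {
      seqc <- seq_chars(arm_sequence(con, arm))
      prev <- ifelse(d$position >= 1L, seqc[pmax(d$position, 1L)], NA)
      keep <- keep & !is.na(prev) & prev == minus1
    }
    if (!any(keep)) next
    pts[[i]] <- data.frame(
      construct = id,
      distance = d$position[keep] - centers$center[1],
      delta = d$delta[keep],
      stringsAsFactors = FALSE
    )
  }
  points <- do.call(rbind, pts)
  if (is.null(points) || !nrow(points)) stop("no poolable points")
  by_d <- do.call(rbind, lapply(split(points$delta, points$distance), function(v) {
    data.frame(
      n = length(v), mean = mean(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75))
    )
  }))
  by_d$distance <- as.integer(rownames(by_d))
  rownames(by_d) <- NULL
  structure(
    list(
      points = points,
      by_distance = by_d[order(by_d$distance), c("distance", "n", "mean", "q25", "q75")],
      arm = arm
    ),
    class = "offset_aggregate"
  )
}

#' LOESS smoothing of pooled points
#'
#' Locally weighted linear regression (degree 1, tricube weights) where
#' `span` is the fraction of points entering each local fit, evaluated at
#' each distinct x.
#'
#' @param x,y Numeric vectors (>= 10 points).
#' @param span Neighbourhood fraction in (0, 1].
#' @return Data.frame with `x` (distinct, sorted) and `fitted`.
#' @export
loess_smooth <- function(x, y, span) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 10L) stop("need at least 10 points for LOESS")
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("span must lie in (0, 1]")
  }
  fit <- stats::loess(y ~ x,
    data = data.frame(x = x, y = y), span = span,
    degree = 1, family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  xs <- sort(unique(x))
  data.frame(x = xs, fitted = stats::predict(fit, newdata = data.frame(x = xs)))
}

#' Attach a smoothed curve to an offset aggregate
#'
#' @param agg An `offset_aggregate`.
#' @param span LOESS span (0.05 for sliding mismatches, 0.11 for bulges,
#'   0.07 for opposite-base series in the screens).
#' @return The aggregate with a `smoothed` element (distance, fitted).
#' @export
smooth_aggregate <- function(agg, span = 0.05) {
  sm <- loess_smooth(agg$points$distance, agg$points$delta, span)
  agg$smoothed <- data.frame(distance = sm$x, fitted = sm$fitted)
  agg$span <- span
  agg
}

#' Locate the induction peak and suppression trough
#'
#' The peak is the argmax of the smoothed delta-editing curve inside
#' `peak_window`, the trough the argmin inside `trough_window`; exact ties
#' break toward the smaller absolute distance. The negative region is the
#' maximal contiguous run of distances with fitted delta < 0 around the
#' trough. A curve whose maximum in the window is not positive is flagged
#' `no_induction`.
#'
#' @param agg A smoothed `offset_aggregate` (see [smooth_aggregate()]); if
#'   unsmoothed, a span-0.05 fit is applied.
#' @param peak_window Search window for the peak (default `c(-45, -15)`,
#'   wide enough for both -26- and -35-class enzymes).
#' @param trough_window Search window for the trough (default `c(-5, 5)`).
#' @return An `offset_call` list: `peak_distance`, `peak_delta`,
#'   `trough_distance`, `trough_delta`, `negative_region`, `no_induction`,
#'   and the windows used.
#' @export
detect_offset_extrema <- function(agg, peak_window = c(-45, -15),
                                  trough_window = c(-5, 5)) {
  if (is.null(agg$smoothed)) agg <- smooth_aggregate(agg, 0.05)
  sm <- agg$smoothed
  rng <- range(sm$distance)
  if (peak_window[1] < rng[1] || peak_window[2] > rng[2]) {
    stop("peak window outside the smoothed curve support")
  }
  if (trough_window[1] < rng[1] || trough_window[2] > rng[2]) {
    stop("trough window outside the smoothed curve support")
  }
  pick_extremum <- function(window, what) {
    w <- sm[sm$distance >= window[1] & sm$distance <= window[2], ]
    v <- if (what == "max") w$fitted else -w$fitted
    best <- which(v == max(v))
    if (length(best) > 1L) best <- best[which.min(abs(w$distance[best]))]
    list(distance = w$distance[best], value = w$fitted[best])
  }
  pk <- pick_extremum(peak_window, "max")
  tr <- pick_extremum(trough_window, "min")
  no_induction <- !(pk$value > 0)
  neg <- sm$fitted < 0
  neg_region <- c(NA_integer_, NA_integer_)
  ti <- match(tr$distance, sm$distance)
  if (neg[ti]) {
    lo <- ti
    while (lo > 1L && neg[lo - 1L]) lo <- lo - 1L
    hi <- ti
    while (hi < length(neg) && neg[hi + 1L]) hi <- hi + 1L
    neg_region <- c(sm$distance[lo], sm$distance[hi])
  }
  structure(
    list(
      peak_distance = if (no_induction) NA_integer_ else pk$distance,
      peak_delta = pk$value,
      trough_distance = tr$distance,
      trough_delta = tr$value,
      negative_region = neg_region,
      no_induction = no_induction,
      peak_window = peak_window,
      trough_window = trough_window
    ),
    class = "offset_call"
  )
}

#' @export
print.offset_call <- function(x, ...) {
  if (x$no_induction) {
    cat("<offset_call> no induction detected\n")
  } else {
    cat(sprintf(
      "<offset_call> peak %+d nt (delta %.2f); trough %+d nt (delta %.2f); negative region [%s, %s]\n",
      x$peak_distance, x$peak_delta, x$trough_distance, x$trough_delta,
      x$negative_region[1], x$negative_region[2]
    ))
  }
  invisible(x)
}

#' Mismatch-size effect at a fixed distance
#'
#' Distribution of delta editing at `at_distance` for each mismatch size.
#'
#' @param aggregates Named list of `offset_aggregate`, one per mismatch
#'   size; names are the sizes (e.g. `"1"`, `"2"`, `"3"`).
#' @param at_distance Signed distance (nt) at which to compare (e.g. -26).
#' @return Data.frame: size, n, median, q25, q75.
#' @export
mismatch_size_effect <- function(aggregates, at_distance) {
  if (is.null(names(aggregates)) || any(!nzchar(names(aggregates)))) {
    stop("aggregates must be a named list keyed by mismatch size")
  }
  out <- lapply(names(aggregates), function(k) {
    pts <- aggregates[[k]]$points
    v <- pts$delta[pts$distance == at_distance]
    if (!length(v)) {
      stop("distance ", at_distance, " absent from the size-", k, " series")
    }
    data.frame(
      size = as.integer(k), n = length(v),
      median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75))
    )
  })
  do.call(rbind, out)
}

#' Editing levels grouped by -1/+1 sequence context
#'
#' Pools per-adenosine editing percentages across profiles and groups them
#' by the base immediately 5' (-1) and 3' (+1) of the adenosine on the
#' quantified strand. Adenosines within `exclude_loop_margin` nt of the
#' loop are excluded.
#'
#' @param profiles Named list of `editing_profile`s.
#' @param library List of `adar_construct`.
#' @param arm Quantified arm.
#' @param exclude_loop_margin Loop-proximal exclusion margin (nt).
#' @return List with `sites` (per-adenosine table with context columns) and
#'   `by_minus1` / `by_plus1` summaries (base, n, median, q25, q75).
#' @export
sequence_context_summary <- function(profiles, library,
                                     arm = c("upper", "lower"),
                                     exclude_loop_margin = 5L) {
  arm <- match.arg(arm)
  rows <- lapply(names(profiles), function(id) {
    prof <- profiles[[id]]
    con <- get_construct(library, id)
    seqc <- seq_chars(arm_sequence(con, arm))
    n <- length(seqc)
    ## the loop adjoins the 3' end of the upper arm, 5' end of the lower
    near_loop <- if (arm == "upper") {
      prof$position >= n - exclude_loop_margin
    } else {
      prof$position < exclude_loop_margin
    }
    keep <- !near_loop & prof$position >= 1L & prof$position <= n - 2L &
      !is.na(prof$percent)
    if (!any(keep)) {
      return(NULL)
    }
    data.frame(
      construct = id,
      position = prof$position[keep],
      minus1 = seqc[prof$position[keep]],
      plus1 = seqc[prof$position[keep] + 2L],
      percent = prof$percent[keep],
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites)) stop("no adenosines left after loop exclusion")
  summarize <- function(f) {
    do.call(rbind, lapply(split(sites$percent, sites[[f]]), function(v) {
      data.frame(
        n = length(v), median = stats::median(v),
        q25 = unname(stats::quantile(v, 0.25)),
        q75 = unname(stats::quantile(v, 0.75))
      )
    }))
  }
  b1 <- summarize("minus1")
  b1$base <- rownames(b1)
  b2 <- summarize("plus1")
  b2$base <- rownames(b2)
  rownames(b1) <- rownames(b2) <- NULL
  list(
    sites = sites,
    by_minus1 = b1[, c("base", "n", "median", "q25", "q75")],
    by_plus1 = b2[, c("base", "n", "median", "q25", "q75")]
  )
}

#' Min-max normalization to [0, 1]
#'
#' @param x Numeric vector.
#' @return Rescaled vector.
#' @export
normalize_minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) stop("degenerate range: all values identical")
  (x - r[1]) / diff(r)
}

#' Construct-by-position delta matrix with per-row z-scores
#'
#' Builds the (construct x adenosine position) delta-editing matrix and
#' z-scores each construct row. Constant rows cannot be z-scored; they are
#' set to `NA` and listed in the `constant_rows` attribute rather than
#' propagating NaN.
#'
#' @param deltas Named list of `delta_profile`s.
#' @return Z-scored matrix with attributes `raw` (unscaled matrix) and
#'   `constant_rows`.
#' @export
delta_zmatrix <- function(deltas) {
  ids <- names(deltas)
  pos <- sort(unique(unlist(lapply(deltas, `[[`, "position"))))
  raw <- matrix(NA_real_, length(ids), length(pos),
    dimnames = list(ids, as.character(pos))
  )
  for (id in ids) {
    d <- deltas[[id]]
    raw[id, as.character(d$position)] <- d$delta
  }
  z <- raw
  constant <- character(0)
  for (id in ids) {
    v <- raw[id, ]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      z[id, ] <- NA_real_
      constant <- c(constant, id)
    } else {
      z[id, ] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  attr(z, "raw") <- raw
  attr(z, "constant_rows") <- constant
  z
}

#' Dose response of mean editing to progressive duplex disruption
#'
#' Mean editing percent per construct of a random-disruption series,
#' min-max normalized across the series (the dose-response readout of the
#' incremental-disruption experiment).
#'
#' @param profiles Named list of `editing_profile`s for the series.
#' @param library List of `adar_construct`.
#' @return Data.frame: construct, fraction, mean_percent, minmax.
#' @export
disruption_dose_response <- function(profiles, library) {
  rows <- lapply(names(profiles), function(id) {
    con <- get_construct(library, id)
    active <- Filter(function(p) p$kind == "random_disruption", con$perturbations)
    if (length(active) != 1L) stop("not a random-disruption construct: ", id)
    data.frame(
      construct = id, fraction = active[[1]]$fraction,
      mean_percent = mean(profiles[[id]]$percent, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$fraction), ]
  df$minmax <- normalize_minmax(df$mean_percent)
  rownames(df) <- NULL
  df
}
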