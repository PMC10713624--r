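#' Parameterize an ADAR-like enzyme
#'
#' An enzyme profile captures the positional editing rules recovered from
#' the hairpin screens: a baseline per-adenosine editing probability on a
#' perfect duplex, a multiplicative induction window at a fixed signed
#' offset upstream of structural disruptions (e.g. -26 nt for ADAR2-like,
#' -35 nt for ADAR1-like enzymes), an optional secondary downstream peak
#' (+30 for ADAR1-like), a per-distance suppression profile over the
#' -26..+29 neighbourhood of a disruption with its minimum at the disrupted
#' register itself, and -1/+1 sequence-context multipliers (G at -1 is
#' strongly disfavoured). An A paired to a C (A-C mismatch) is boosted
#' rather than suppressed.
#'
#' @param name Profile name.
#' @param baseline_edit_prob Editing probability per adenosine on a perfect
#'   duplex, in `[0, 1]`.
#' @param induction_offset Signed offset (nt) of the induction peak;
#'   negative = the adenosine lies 5' of the disruption on its own strand.
#' @param induction_halfwidth Half-width (nt) of the induction window.
#' @param induction_fold Fold-change at the induction peak (>= 1).
#' @param downstream_offset Optional secondary peak offset (e.g. +30).
#' @param downstream_fold Fold-change at the secondary peak.
#' @param suppression_profile Named numeric vector of multipliers in
#'   `[0, 1]` over distances -26..+29 (names are the distances); see
#'   [default_suppression()].
#' @param context_multipliers 4x4 numeric matrix, rows = -1 base, columns =
#'   +1 base (A, C, G, T); see [default_context()].
#' @param symmetric Logical; if `TRUE`, editing is also induced on the
#'   lower arm with distances measured on its own strand.
#' @param ac_boost Multiplier applied to an adenosine opposite a C instead
#'   of the suppression minimum.
#' @return An `enzyme_profile`.
#' @export
enzyme_profile <- function(name, baseline_edit_prob,
                           induction_offset = -26L,
                           induction_halfwidth = 3L,
                           induction_fold = 1.4,
                           downstream_offset = NULL,
                           downstream_fold = 1,
                           suppression_profile = default_suppression("+1"),
                           context_multipliers = default_context(),
                           symmetric = FALSE,
                           ac_boost = 1.5) {
  stopifnot(
    baseline_edit_prob >= 0, baseline_edit_prob <= 1,
    induction_fold >= 1, induction_halfwidth >= 0,
    all(suppression_profile >= 0), all(suppression_profile <= 1)
  )
  dists <- as.integer(names(suppression_profile))
  if (length(dists) && any(suppression_profile < 1)) {
    m <- dists[which.min(suppression_profile)]
    if (!m %in% c(0L, 1L)) {
      stop("suppression profile minimum must lie at distance 0 or +1")
    }
  }
  structure(
    list(
      name = name,
      baseline_edit_prob = baseline_edit_prob,
      induction_offset = as.integer(induction_offset),
      induction_halfwidth = as.integer(induction_halfwidth),
      induction_fold = induction_fold,
      downstream_offset = if (is.null(downstream_offset)) {
        NULL
      } else {
        as.integer(downstream_offset)
      },
      downstream_fold = downstream_fold,
      suppression_profile = suppression_profile,
      context_multipliers = context_multipliers,
      symmetric = isTRUE(symmetric),
      ac_boost = ac_boost
    ),
    class = "enzyme_profile"
  )
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cat(sprintf(
    "<enzyme_profile '%s'> baseline %.2f, peak %+d nt (fold %.1f)%s%s\n",
    x$name, x$baseline_edit_prob, x$induction_offset, x$induction_fold,
    if (!is.null(x$downstream_offset)) {
      sprintf(", secondary %+d (fold %.1f)", x$downstream_offset, x$downstream_fold)
    } else {
      ""
    },
    if (x$symmetric) ", symmetric" else ""
  ))
  invisible(x)
}

#' Default per-distance suppression profile
#'
#' Piecewise-linear multipliers over distances -26..+29 relative to a
#' disruption: minimum (near 0) at the disrupted register, partial local
#' maxima at -9 and +6/+7, an extra local maximum at +15 for ADAR2-like
#' enzymes, and full recovery at the window edges. Magnitudes at the local
#' maxima are a package modelling choice; only the window extent, the
#' minimum location and the local-maximum positions are constrained by the
#' screen.
#'
#' @param min_at `"0"` (ADAR1-like) or `"+1"` (ADAR2-like): the distance at
#'   which suppression is maximal.
#' @return Named numeric vector over distances -26..+29.
#' @export
default_suppression <- function(min_at = c("+1", "0")) {
  min_at <- match.arg(min_at)
  anchors_x <- c(-26, -20, -13, -9, -4, 0, 1, 4, 6, 7, 10, 15, 20, 25, 29)
  if (min_at == "+1") {
    ## ADAR2-like: minimum at +1, local maximum at +15
    anchors_y <- c(1, .75, .45, .65, .25, .05, 0, .30, .55, .55, .35, .60, .45, .85, 1)
  } else {
    anchors_y <- c(1, .75, .45, .65, .25, 0, .05, .30, .55, .55, .35, .40, .55, .85, 1)
  }
  d <- -26:29
  s <- stats::approx(anchors_x, anchors_y, xout = d)$y
  stats::setNames(s, d)
}

#' Flat (inactive) suppression profile
#'
#' @return Named vector of 1s over -26..+29 except a token minimum of 1 at 0.
#' @export
flat_suppression <- function() {
  stats::setNames(rep(1, 56), -26:29)
}

#' Default -1/+1 sequence-context multipliers
#'
#' G immediately upstream of the edited adenosine is strongly disfavoured;
#' other neighbours are close to neutral.
#'
#' @return 4x4 matrix (rows: -1 base, columns: +1 base, order A,C,G,T).
#' @export
default_context <- function() {
  minus1 <- c(A = 1.1, C = 1.0, G = 0.3, T = 1.0)
  plus1 <- c(A = 1.0, C = 1.0, G = 1.05, T = 0.95)
  outer(minus1, plus1)
}

#' Neutral context multipliers
#' @return 4x4 matrix of ones.
#' @export
neutral_context <- function() {
  matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
}

#' Packaged enzyme presets
#'
#' Presets mirror the enzyme repertoire of the hairpin screens: human ADAR2
#' (-26), human ADAR1 (-35 with a +30 secondary peak), the two RBD-swap
#' hybrids (-35 and -30), and the Octopus (-28) and Suricata (-35)
#' homologs, plus a `"null"` enzyme (flat rules) for negative controls.
#' Induction folds sit inside the fold ranges reported for the screens
#' (~1.3-1.5 at -26, ~3.3-6 at -35); baselines reflect roughly half of
#' adenosines edited per molecule for ADAR2 and slightly fewer for ADAR1.
#'
#' @param name Preset name.
#' @param symmetric Override the symmetric-editing flag.
#' @return An [enzyme_profile()].
#' @export
#' @examples
#' adar_profile("adar2")
adar_profile <- function(name = c(
                           "adar2", "adar1", "adar1_rbd_adar2_deam",
                           "adar2_rbd_adar1_deam", "octopus", "suricata",
                           "null"
                         ),
                         symmetric = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    adar2 = enzyme_profile("adar2",
      baseline_edit_prob = 0.5,
      induction_offset = -26L, induction_fold = 1.4,
      suppression_profile = default_suppression("+1"),
      symmetric = TRUE
    ),
    adar1 = enzyme_profile("adar1",
      baseline_edit_prob = 0.4,
      induction_offset = -35L, induction_fold = 4,
      downstream_offset = 30L, downstream_fold = 1.5,
      suppression_profile = default_suppression("0"),
      symmetric = TRUE
    ),
    adar1_rbd_adar2_deam = enzyme_profile("adar1_rbd_adar2_deam",
      baseline_edit_prob = 0.25,
      induction_offset = -35L, induction_fold = 3,
      suppression_profile = default_suppression("+1"),
      symmetric = TRUE
    ),
    adar2_rbd_adar1_deam = enzyme_profile("adar2_rbd_adar1_deam",
      baseline_edit_prob = 0.25,
      induction_offset = -30L, induction_fold = 1.4,
      suppression_profile = default_suppression("0"),
      symmetric = TRUE
    ),
    octopus = enzyme_profile("octopus",
      baseline_edit_prob = 0.35,
      induction_offset = -28L, induction_fold = 1.5,
      suppression_profile = default_suppression("+1"),
      symmetric = TRUE
    ),
    suricata = enzyme_profile("suricata",
      baseline_edit_prob = 0.35,
      induction_offset = -35L, induction_fold = 3,
      suppression_profile = default_suppression("0"),
      symmetric = TRUE
    ),
    null = enzyme_profile("null",
      baseline_edit_prob = 0.5,
      induction_offset = -26L, induction_fold = 1,
      suppression_profile = flat_suppression(),
      context_multipliers = neutral_context(),
      symmetric = TRUE, ac_boost = 1
    )
  )
  if (!is.null(symmetric)) p$symmetric <- isTRUE(symmetric)
  p
}

## triangular induction kernel: 1 at the offset, 0 beyond halfwidth + 1
tri_kernel <- function(d, offset, halfwidth) {
  pmax(0, 1 - abs(d - offset) / (halfwidth + 1))
}

#' True editing probability of an adenosine under an enzyme model
#'
#' Combines baseline, sequence context, distance-dependent induction and
#' suppression into a clamped probability:
#' `clamp(baseline * context * induction * suppression)`. Distances are
#' measured on the adenosine's own strand to each disruption center
#' (negative = adenosine 5' of the disruption). With several disruptions
#' the strongest induction and the strongest suppression apply. An
#' adenosine directly opposite a C is boosted (`ac_boost`) instead of
#' suppressed.
#'
#' @param construct An `adar_construct`.
#' @param profile An [enzyme_profile()].
#' @param position 0-based adenosine position(s) on `arm` (vectorized).
#' @param arm `"upper"` or `"lower"`.
#' @return Numeric vector of editing probabilities.
#' @export
editing_probability <- function(construct, profile, position,
                                arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  a_pos <- arm_adenosines(construct, arm)
  if (!all(position %in% a_pos)) {
    bad <- setdiff(position, a_pos)
    stop(
      "position(s) not adenosines on the ", arm, " arm: ",
      paste(bad, collapse = ", ")
    )
  }
  if (arm == "lower" && !profile$symmetric) {
    return(rep(0, length(position)))
  }
  seqc <- seq_chars(arm_sequence(construct, arm))
  centers <- disruption_centers(construct, arm)
  supp <- profile$suppression_profile
  supp_d <- as.integer(names(supp))
  vapply(position, function(pos) {
    ctx_m1 <- if (pos >= 1L) seqc[pos] else NA_character_
    ctx_p1 <- if (pos + 2L <= length(seqc)) seqc[pos + 2L] else NA_character_
    ctx <- 1
    if (!is.na(ctx_m1) && !is.na(ctx_p1)) {
      ctx <- profile$context_multipliers[ctx_m1, ctx_p1]
    } else if (!is.na(ctx_m1)) {
      ctx <- mean(profile$context_multipliers[ctx_m1, ])
    } else if (!is.na(ctx_p1)) {
      ctx <- mean(profile$context_multipliers[, ctx_p1])
    }
    induction <- 1
    suppression <- 1
    if (nrow(centers)) {
      d <- pos - centers$center
      f <- 1 + (profile$induction_fold - 1) *
        tri_kernel(d, profile$induction_offset, profile$induction_halfwidth)
      if (!is.null(profile$downstream_offset)) {
        f2 <- 1 + (profile$downstream_fold - 1) *
          tri_kernel(d, profile$downstream_offset, profile$induction_halfwidth)
        f <- pmax(f, f2)
      }
      induction <- max(f)
      s <- rep(1, length(d))
      inside <- d %in% supp_d
      s[inside] <- supp[match(d[inside], supp_d)]
      ## an A-C pair boosts rather than suppresses its own register
      ac <- d == 0L & !is.na(centers$opposite) & centers$opposite == "C"
      s[ac] <- 1
      suppression <- min(s) * if (any(ac)) profile$ac_boost else 1
    }
    min(1, max(0, profile$baseline_edit_prob * ctx * induction * suppression))
  }, numeric(1))
}
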