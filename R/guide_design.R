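#' Design an ADAR-recruiting guide RNA (arRNA)
#'
#' All non-empty modes start from the 151-nt positive-control scaffold: the
#' exact reverse complement of the 151-nt target window centered on the
#' target adenosine, with a C placed opposite the target A (75 + 1 + 75
#' layout, guide position 75 opposite the A). Modes add engineered
#' mismatches on top:
#' * `adar2_offset`: a 3-nt duplex disruption whose near edge sits
#'   `offset_distance` (default 26) bp 3' of the target A on its own
#'   strand, so the A lies at the ADAR2 induction offset (-26) relative to
#'   the disruption;
#' * `adar1_offset`: a 4-nt disruption at 35 bp, matching the ADAR1 rule;
#' * `minus1_GA` / `minus1_GG`: the guide base opposite the target's -1 G
#'   set to A or G (requires a G immediately 5' of the target A);
#' * `central_3nt`: a 3-nt mismatch centered on the target A;
#' * `positive_control`: scaffold only; `empty`: no guide.
#'
#' Engineered mismatch bases follow the X-opposite-X rule (guide base set
#' to the identity of the opposing target base), which never creates new
#' editable A-C pairs.
#'
#' @param target_window Target-strand sequence (>= 151 nt of centered
#'   coverage around the A).
#' @param target_a_index 0-based index of the edited A in `target_window`.
#' @param mode Design mode.
#' @param offset_distance Distance (bp) from the target A to the near edge
#'   of the offset disruption (26, or 27 via this argument).
#' @param offset_size Disruption length for `adar2_offset` (default 3).
#' @return A `guide_design`: `guide_sequence` (151 nt or `NA` for
#'   `empty`), `window` (the 151-nt target subwindow), `target_a_index`
#'   (position of the A inside that window, always 75), `mode`, and
#'   `engineered_mismatches` (data.frame: target_offset — register
#'   relative to the A —, guide_base, target_base).
#' @export
design_guide <- function(target_window, target_a_index,
                         mode = c(
                           "positive_control", "adar2_offset",
                           "adar1_offset", "minus1_GA", "minus1_GG",
                           "central_3nt", "empty"
                         ),
                         offset_distance = 26L, offset_size = 3L) {
  mode <- match.arg(mode)
  target_window <- normalize_seq(target_window, "target window")
  n <- nchar(target_window)
  if (target_a_index < 0L || target_a_index >= n) {
    stop("target_a_index outside the window")
  }
  if (substr(
    target_window, target_a_index + 1L,
    target_a_index + 1L
  ) != "A") {
    stop("base at target_a_index is not A")
  }
  if (mode == "empty") {
    return(structure(
      list(
        guide_sequence = NA_character_, window = NA_character_,
        target_a_index = NA_integer_, mode = mode,
        engineered_mismatches = data.frame()
      ),
      class = "guide_design"
    ))
  }
  flank <- 75L
  if (target_a_index < flank || target_a_index + flank >= n) {
    stop("window too short: need 75 nt on each side of the target A")
  }
  win <- substr(
    target_window, target_a_index - flank + 1L,
    target_a_index + flank + 1L
  )
  winc <- seq_chars(win)
  a_idx <- flank # 0-based index of the A inside the 151-nt window
  ## registers of engineered mismatches, relative to the target A
  mm_off <- switch(mode,
    positive_control = integer(0),
    adar2_offset = {
      if (offset_distance + offset_size - 1L > flank) {
        stop("requested disruption lies outside the 75-nt flank")
      }
      offset_distance + 0L:(offset_size - 1L)
    },
    adar1_offset = {
      if (35L + 3L > flank) stop("requested disruption lies outside the 75-nt flank")
      35L + 0L:3L
    },
    minus1_GA = ,
    minus1_GG = {
      if (winc[a_idx] != "G") stop("no upstream G: target -1 base is not G")
      -1L
    },
    central_3nt = c(-1L, 1L)
  )
  ## guide_at[i]: the base the guide presents opposite window position i;
  ## start fully complementary, then place the central C opposite the A
  guide_at <- vapply(winc, complement_base, character(1), USE.NAMES = FALSE)
  guide_at[a_idx + 1L] <- "C"
  mism <- list(list(
    target_offset = 0L, guide_base = "C",
    target_base = "A"
  ))
  for (off in mm_off) {
    i <- a_idx + off + 1L
    tb <- winc[i]
    gb <- if (mode %in% c("minus1_GA", "minus1_GG")) {
      if (mode == "minus1_GA") "A" else "G"
    } else {
      tb # X-opposite-X
    }
    if (gb == complement_base(tb)) {
      stop("engineered base would be complementary to the target")
    }
    guide_at[i] <- gb
    mism[[length(mism) + 1L]] <- list(
      target_offset = off,
      guide_base = gb, target_base = tb
    )
  }
  ## guide_at[i] is the guide base presented opposite window position i
  ## (antiparallel): the guide sequence 5'->3' is that vector reversed
  guide_seq <- paste(rev(guide_at), collapse = "")
  mism_df <- do.call(rbind, lapply(mism, as.data.frame))
  mism_df <- mism_df[order(mism_df$target_offset), ]
  rownames(mism_df) <- NULL
  structure(
    list(
      guide_sequence = guide_seq, window = win,
      target_a_index = a_idx, mode = mode,
      offset_distance = if (mode %in% c("adar2_offset", "adar1_offset")) {
        if (mode == "adar1_offset") 35L else as.integer(offset_distance)
      } else {
        NA_integer_
      },
      engineered_mismatches = mism_df
    ),
    class = "guide_design"
  )
}

#' @export
print.guide_design <- function(x, ...) {
  if (x$mode == "empty") {
    cat("<guide_design> empty vector (no guide)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<guide_design> mode %s, %d nt, %d engineered mismatch register(s)\n",
    x$mode, nchar(x$guide_sequence), nrow(x$engineered_mismatches)
  ))
  invisible(x)
}

#' Map duplex registers between target and guide coordinates
#'
#' The 151-nt guide anneals antiparallel to the 151-nt target window:
#' target window position `t` (0-based) pairs with guide position
#' `150 - t`; the target A (window position 75) pairs with guide position
#' 75. Signed distances relative to the target A follow the offset
#' convention (negative = 5' of the A on the target strand).
#'
#' @param design A `guide_design` (non-empty).
#' @param target_position 0-based position(s) in the 151-nt window.
#' @return Data.frame: target_position, guide_position, distance (signed,
#'   relative to the target A).
#' @export
duplex_register_map <- function(design, target_position = 0:150) {
  if (design$mode == "empty") stop("empty design has no duplex")
  L <- nchar(design$guide_sequence)
  if (any(target_position < 0L | target_position >= L)) {
    stop("target position outside the duplex")
  }
  data.frame(
    target_position = target_position,
    guide_position = L - 1L - target_position,
    distance = target_position - design$target_a_index
  )
}

#' Predict off-target adenosines of a guide design
#'
#' Flags target-strand adenosines (other than the target A) whose signed
#' distance to any engineered duplex disruption (including the central A-C)
#' matches the enzyme's induction offset within its halfwidth. Induction by
#' ADARs is symmetric across the duplex, so both the canonical side (the
#' adenosine upstream of the disruption on its own strand, tag
#' `upstream_induction`) and the mirror-image side (tag `mirror_induction`)
#' are flagged. Adenosines rendered unpaired by an engineered disruption
#' are reported as `depleted` instead.
#'
#' @param design A `guide_design`.
#' @param profile An [enzyme_profile()].
#' @return Data.frame: `distance` (register relative to the target A),
#'   `position` (0-based in the window), `predicted`, `mechanism`.
#' @export
predict_offtargets <- function(design, profile) {
  if (design$mode == "empty") {
    return(data.frame(
      distance = integer(0), position = integer(0),
      predicted = logical(0), mechanism = character(0)
    ))
  }
  winc <- seq_chars(design$window)
  a_idx <- design$target_a_index
  a_pos <- which(winc == "A") - 1L
  a_pos <- setdiff(a_pos, a_idx)
  mm <- design$engineered_mismatches
  calls <- list()
  off <- profile$induction_offset
  hw <- profile$induction_halfwidth
  for (p in a_pos) {
    d_to_a <- p - a_idx
    if (d_to_a %in% mm$target_offset) {
      calls[[length(calls) + 1L]] <- data.frame(
        distance = d_to_a, position = p, predicted = TRUE,
        mechanism = "depleted", stringsAsFactors = FALSE
      )
      next
    }
    d <- d_to_a - mm$target_offset # signed distance to each disruption
    if (any(abs(d - off) <= hw)) {
      calls[[length(calls) + 1L]] <- data.frame(
        distance = d_to_a, position = p, predicted = TRUE,
        mechanism = "upstream_induction", stringsAsFactors = FALSE
      )
    } else if (any(abs(d + off) <= hw)) {
      calls[[length(calls) + 1L]] <- data.frame(
        distance = d_to_a, position = p, predicted = TRUE,
        mechanism = "mirror_induction", stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) {
    return(data.frame(
      distance = integer(0), position = integer(0),
      predicted = logical(0), mechanism = character(0)
    ))
  }
  do.call(rbind, calls)
}

#' Represent a guide:target duplex as a reporter-style construct
#'
#' Builds a loop-less duplex construct whose upper arm is the 151-nt target
#' window and whose lower arm is the guide, with the engineered mismatches
#' expressed as perturbations, so the read simulator and quantifier can be
#' run on targeted-editing designs.
#'
#' @param design A non-empty `guide_design`.
#' @param id Construct id (default the design mode).
#' @param barcode Optional 8-nt barcode.
#' @return An `adar_construct`.
#' @export
guide_duplex_construct <- function(design, id = design$mode,
                                   barcode = NA_character_) {
  if (design$mode == "empty") stop("empty design has no duplex")
  backbone <- build_backbone(design$window, "", name = "guide_duplex")
  mm <- design$engineered_mismatches
  perts <- lapply(seq_len(nrow(mm)), function(i) {
    perturbation("opposite_base",
      position = design$target_a_index + mm$target_offset[i],
      length = 1L,
      payload = mm$guide_base[i]
    )
  })
  con <- new_construct(backbone, perts, id = id, barcode = barcode)
  if (!is.na(barcode)) {
    con$full_sequence <- paste0(
      con$upper_arm, con$loop, con$lower_arm,
      barcode
    )
  }
  con
}

#' Quantify editing across an amplicon and call off-targets
#'
#' Computes `100 * G / (A + G)` at every adenosine of a reference window
#' from reads spanning it, and reports non-target adenosines edited above
#' `offtarget_threshold` percent.
#'
#' @param reads Character vector of read sequences (or a FASTQ path), each
#'   aligned to and spanning the full reference window.
#' @param reference Reference window sequence (target strand).
#' @param target_a_index 0-based position of the targeted A.
#' @param offtarget_threshold Off-target call threshold (percent).
#' @return List with `table` (position, a, g, percent, is_target) and
#'   `offtargets` (rows above threshold).
#' @export
quantify_amplicon <- function(reads, reference, target_a_index,
                              offtarget_threshold = 2.0) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  reference <- normalize_seq(reference, "reference")
  n <- nchar(reference)
  reads <- reads[nchar(reads) == n]
  if (!length(reads)) stop("no reads span the reference window")
  refc <- seq_chars(reference)
  a_pos <- which(refc == "A") - 1L
  if (!(target_a_index %in% a_pos)) stop("target_a_index is not an A")
  a_n <- integer(length(a_pos))
  g_n <- integer(length(a_pos))
  for (j in seq_along(a_pos)) {
    b <- substr(reads, a_pos[j] + 1L, a_pos[j] + 1L)
    a_n[j] <- sum(b == "A")
    g_n[j] <- sum(b == "G")
  }
  tab <- data.frame(
    position = a_pos, a = a_n, g = g_n,
    percent = editing_percent(a_n, g_n),
    is_target = a_pos == target_a_index
  )
  ot <- tab[!tab$is_target & !is.na(tab$percent) &
    tab$percent > offtarget_threshold, , drop = FALSE]
  list(table = tab, offtargets = ot)
}
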