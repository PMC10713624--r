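#' Build a hairpin reporter backbone
#'
#' A reporter hairpin consists of a constant (sequenced) upper arm, a loop,
#' and a lower arm that is the exact reverse complement of the upper arm.
#' With the default geometry (146-bp stem, 46-nt loop) the full hairpin is
#' 338 nt long. All structural perturbations are applied to the lower arm so
#' the upper arm stays constant across a library.
#'
#' @param upper_arm Upper (constant) arm sequence, 5'->3'.
#' @param loop Loop sequence (may be empty for a plain duplex).
#' @param name Backbone identifier.
#' @return An object of class `hairpin_backbone` with elements `name`,
#'   `upper_arm`, `loop`, `lower_arm`, `stem_length`.
#' @export
#' @examples
#' bb <- build_backbone("GGGG", "AAAA")
#' bb$lower_arm  # "CCCC"
build_backbone <- function(upper_arm, loop = "", name = "backbone") {
  upper_arm <- normalize_seq(upper_arm, "upper_arm")
  if (nchar(upper_arm) == 0L) stop("upper_arm must be non-empty")
  loop <- normalize_seq(loop, "loop")
  structure(
    list(
      name = name,
      upper_arm = upper_arm,
      loop = loop,
      lower_arm = revcomp(upper_arm),
      stem_length = nchar(upper_arm)
    ),
    class = "hairpin_backbone"
  )
}

#' @export
print.hairpin_backbone <- function(x, ...) {
  cat(sprintf(
    "<hairpin_backbone '%s'> stem %d bp, loop %d nt, total %d nt\n",
    x$name, x$stem_length, nchar(x$loop),
    2L * x$stem_length + nchar(x$loop)
  ))
  invisible(x)
}

#' Default example backbone
#'
#' Deterministically generates a synthetic 146-nt upper arm with exactly 44
#' adenosines (mirroring the adenosine content of the synthetic mNG-derived
#' reporter) and a 46-nt loop. This is a synthetic stand-in sequence; the
#' published reporter sequences are not reproduced.
#'
#' @param seed Integer seed controlling the arm sequence.
#' @param stem_length Stem length in bp.
#' @param loop_length Loop length in nt.
#' @param n_adenosines Number of adenosines placed on the upper arm.
#' @return A `hairpin_backbone`.
#' @export
example_backbone <- function(seed = 20230426L, stem_length = 146L,
                             loop_length = 46L, n_adenosines = 44L) {
  stopifnot(n_adenosines <= stem_length)
  old <- .Random.seed_guard(seed)
  on.exit(old())
  n_t <- min(stem_length - n_adenosines, n_adenosines)
  n_cg <- stem_length - n_adenosines - n_t
  pool <- c(
    rep("A", n_adenosines), rep("T", n_t),
    rep(c("C", "G"), length.out = n_cg)
  )
  upper <- paste(sample(pool), collapse = "")
  loop <- paste(sample(DNA_BASES, loop_length, replace = TRUE), collapse = "")
  build_backbone(upper, loop, name = sprintf("synthetic_mNG_like_seed%d", seed))
}

## Save/restore RNG state so deterministic helpers do not perturb the
## caller's random stream.
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Library design configuration
#'
#' Houses the design constants of a perturbation library: hairpin geometry,
#' barcode constraints and the default perturbation repertoire.
#'
#' @param stem_length Stem length in bp (default 146).
#' @param loop_length Loop length in nt (default 46).
#' @param barcode_length Barcode length in nt (default 8).
#' @param min_barcode_hamming Minimum pairwise Hamming distance among
#'   barcodes (default 2).
#' @param mismatch_sizes Mismatch sizes for sliding-mismatch series.
#' @param bulge_sequence Bulge insert (default the pyrimidine-rich
#'   `"TTCTTCT"`).
#' @param disruption_fractions Fractions for the random-disruption series
#'   (default 5\% steps up to 100\%).
#' @param rng_seed Seed governing barcode assignment and random disruptions.
#' @return A `library_config` list.
#' @export
library_config <- function(stem_length = 146L, loop_length = 46L,
                           barcode_length = 8L, min_barcode_hamming = 2L,
                           mismatch_sizes = c(1L, 2L, 3L),
                           bulge_sequence = "TTCTTCT",
                           disruption_fractions = seq(0.05, 1, by = 0.05),
                           rng_seed = 1L) {
  stopifnot(
    stem_length > 0, loop_length >= 0, barcode_length > 0,
    all(mismatch_sizes >= 1), all(disruption_fractions > 0),
    all(disruption_fractions <= 1)
  )
  structure(
    list(
      stem_length = as.integer(stem_length),
      loop_length = as.integer(loop_length),
      barcode_length = as.integer(barcode_length),
      min_barcode_hamming = as.integer(min_barcode_hamming),
      mismatch_sizes = as.integer(mismatch_sizes),
      bulge_sequence = normalize_seq(bulge_sequence, "bulge_sequence"),
      disruption_fractions = disruption_fractions,
      rng_seed = as.integer(rng_seed)
    ),
    class = "library_config"
  )
}

#' Describe a single structural perturbation
#'
#' Positions are 0-based registers on the duplex: register `r` is position
#' `r` of the upper arm and the base pairing it on the lower arm.
#' Perturbations are applied to the lower arm only.
#'
#' @param kind One of `"mismatch"`, `"bulge"`, `"opposite_base"`,
#'   `"random_disruption"`.
#' @param position 0-based start register (insertion register for bulges).
#' @param length Perturbation length in nt (mismatch size, bulge insert
#'   length).
#' @param payload Bulge insert sequence or the base placed opposite an
#'   adenosine.
#' @param fraction Disrupted stem fraction for `random_disruption`.
#' @param seed RNG seed for `random_disruption` base choices.
#' @return A `perturbation` list.
#' @export
perturbation <- function(kind, position = NA_integer_, length = NA_integer_,
                         payload = NA_character_, fraction = NA_real_,
                         seed = NA_integer_) {
  kind <- match.arg(kind, c(
    "mismatch", "bulge", "opposite_base",
    "random_disruption", "none"
  ))
  structure(
    list(
      kind = kind, position = as.integer(position),
      length = as.integer(length), payload = payload,
      fraction = fraction, seed = as.integer(seed)
    ),
    class = "perturbation"
  )
}

## Applies a perturbation list to a backbone, returning the perturbed lower
## arm plus bookkeeping: perturbed upper-scale registers and the new base
## opposite each perturbed register.
apply_perturbations <- function(backbone, perturbations) {
  ls0 <- backbone$stem_length
  upper <- seq_chars(backbone$upper_arm)
  lower <- seq_chars(backbone$lower_arm)
  registers <- list()
  opposite <- list()
  inserts <- list() # collected last so indices stay on the register scale
  for (i in seq_along(perturbations)) {
    p <- perturbations[[i]]
    if (p$kind == "none") {
      registers[[i]] <- integer(0)
      opposite[[i]] <- character(0)
      next
    }
    if (p$kind == "mismatch") {
      k <- p$length
      r <- p$position
      if (is.na(k) || k < 1L) stop("mismatch length must be >= 1")
      if (r < 0L || r + k > ls0) stop("mismatch exceeds the stem")
      regs <- r:(r + k - 1L)
      ## X-opposite-X rule: lower base set to the identity of its upper
      ## partner, guaranteeing a mismatch without creating A-C pairs.
      newb <- upper[regs + 1L]
      lower[ls0 - regs] <- newb
      registers[[i]] <- regs
      opposite[[i]] <- stats::setNames(newb, regs)
    } else if (p$kind == "opposite_base") {
      r <- p$position
      b <- normalize_seq(p$payload, "opposite base")
      if (nchar(b) != 1L) stop("opposite_base payload must be one base")
      if (r < 0L || r >= ls0) stop("opposite_base position outside the stem")
      lower[ls0 - r] <- b
      registers[[i]] <- r
      opposite[[i]] <- stats::setNames(b, r)
    } else if (p$kind == "bulge") {
      ins <- normalize_seq(p$payload, "bulge payload")
      if (nchar(ins) == 0L) stop("bulge payload must be non-empty")
      r <- p$position
      if (r < 0L || r > ls0) stop("bulge insertion register outside the stem")
      ## insert on the lower arm between the partners of registers r-1 and r
      inserts[[length(inserts) + 1L]] <- list(at = ls0 - r, seq = ins)
      registers[[i]] <- r
      opposite[[i]] <- character(0)
    } else if (p$kind == "random_disruption") {
      frac <- p$fraction
      if (is.na(frac) || frac <= 0 || frac > 1) {
        stop("random_disruption fraction must be in (0, 1]")
      }
      n_sub <- ceiling(frac * ls0)
      old <- .Random.seed_guard(if (is.na(p$seed)) 0L else p$seed)
      regs <- sort(sample.int(ls0, n_sub) - 1L)
      ## substitute with one of the two bases that neither pair with nor
      ## match the upper base
      newb <- vapply(regs, function(r) {
        u <- upper[r + 1L]
        sample(setdiff(DNA_BASES, c(u, complement_base(u))), 1L)
      }, character(1))
      old()
      lower[ls0 - regs] <- newb
      registers[[i]] <- regs
      opposite[[i]] <- stats::setNames(newb, regs)
    }
    perturbations[[i]]$registers <- registers[[i]]
    perturbations[[i]]$opposite <- opposite[[i]]
  }
  ## apply bulge insertions (descending position keeps earlier indices valid)
  lower_seq <- paste(lower, collapse = "")
  if (length(inserts)) {
    ord <- order(vapply(inserts, `[[`, numeric(1), "at"), decreasing = TRUE)
    for (ins in inserts[ord]) {
      lower_seq <- paste0(
        substr(lower_seq, 1L, ins$at),
        ins$seq,
        substr(lower_seq, ins$at + 1L, nchar(lower_seq))
      )
    }
  }
  list(lower_arm = lower_seq, perturbations = perturbations)
}

#' Assemble a construct from a backbone and perturbations
#'
#' @param backbone A `hairpin_backbone`.
#' @param perturbations List of [perturbation()] objects (possibly empty).
#' @param id Construct identifier.
#' @param barcode Optional 8-nt barcode (usually assigned later by
#'   [assign_barcodes()]).
#' @return An `adar_construct`: the perturbed hairpin plus 0-based adenosine
#'   positions on each arm.
#' @export
new_construct <- function(backbone, perturbations = list(), id,
                          barcode = NA_character_) {
  stopifnot(inherits(backbone, "hairpin_backbone"))
  ap <- apply_perturbations(backbone, perturbations)
  hairpin <- paste0(backbone$upper_arm, backbone$loop, ap$lower_arm)
  structure(
    list(
      id = id,
      backbone_name = backbone$name,
      upper_arm = backbone$upper_arm,
      loop = backbone$loop,
      lower_arm = ap$lower_arm,
      stem_length = backbone$stem_length,
      barcode = barcode,
      perturbations = ap$perturbations,
      a_pos_upper = adenosine_positions(backbone$upper_arm),
      a_pos_lower = adenosine_positions(ap$lower_arm),
      full_sequence = if (is.na(barcode)) hairpin else paste0(hairpin, barcode)
    ),
    class = "adar_construct"
  )
}

#' @export
print.adar_construct <- function(x, ...) {
  kinds <- vapply(x$perturbations, `[[`, character(1), "kind")
  cat(sprintf(
    "<adar_construct '%s'> stem %d bp, %d perturbation(s)%s, barcode %s\n",
    x$id, x$stem_length, length(kinds),
    if (length(kinds)) paste0(" [", paste(kinds, collapse = ","), "]") else "",
    ifelse(is.na(x$barcode), "<unassigned>", x$barcode)
  ))
  invisible(x)
}

#' Perfect-duplex reference construct
#'
#' The unperturbed hairpin serving as the reference for delta-editing.
#'
#' @param backbone A `hairpin_backbone`.
#' @param id Identifier (default `"perfect"`).
#' @return An `adar_construct` with no perturbations.
#' @export
reference_construct <- function(backbone, id = "perfect") {
  new_construct(backbone, list(), id = id)
}

#' Generate a systematic perturbation series
#'
#' Produces, from one backbone, the construct series of the reporter screen:
#' * `mismatch`: a `size`-nt mismatch slid base by base along the stem
#'   (`stem_length - size + 1` constructs);
#' * `bulge`: the `payload` insert placed at every insertion register of the
#'   lower arm (`stem_length` constructs);
#' * `opposite_base`: one construct per upper-arm adenosine with `base`
#'   placed opposite it;
#' * `random_disruption`: one construct per disruption fraction, with
#'   `ceiling(fraction * stem_length)` lower-arm registers substituted to
#'   non-pairing bases.
#'
#' @param backbone A `hairpin_backbone`.
#' @param kind Series kind.
#' @param config A [library_config()].
#' @param size Mismatch size (nt) for `kind = "mismatch"`.
#' @param payload Insert sequence for `kind = "bulge"` (default from config).
#' @param base Base placed opposite adenosines for `kind = "opposite_base"`.
#' @return List of `adar_construct` (no barcodes yet).
#' @export
#' @examples
#' bb <- example_backbone()
#' series <- generate_series(bb, "mismatch", size = 3)
#' length(series)  # 144
generate_series <- function(backbone, kind, config = library_config(),
                            size = 3L, payload = config$bulge_sequence,
                            base = "C") {
  kind <- match.arg(kind, c(
    "mismatch", "bulge", "opposite_base",
    "random_disruption"
  ))
  ls0 <- backbone$stem_length
  if (kind == "mismatch") {
    size <- as.integer(size)
    if (size > ls0) stop("mismatch size exceeds the stem length")
    starts <- 0L:(ls0 - size)
    lapply(starts, function(r) {
      new_construct(
        backbone,
        list(perturbation("mismatch", position = r, length = size)),
        id = sprintf("mm%d_p%03d", size, r)
      )
    })
  } else if (kind == "bulge") {
    payload <- normalize_seq(payload, "bulge payload")
    if (nchar(payload) == 0L) stop("bulge payload must be non-empty")
    lapply(0L:(ls0 - 1L), function(r) {
      new_construct(
        backbone,
        list(perturbation("bulge",
          position = r,
          length = nchar(payload), payload = payload
        )),
        id = sprintf("bulge_p%03d", r)
      )
    })
  } else if (kind == "opposite_base") {
    base <- normalize_seq(base, "opposite base")
    a_pos <- adenosine_positions(backbone$upper_arm)
    lapply(a_pos, function(r) {
      new_construct(
        backbone,
        list(perturbation("opposite_base",
          position = r, length = 1L,
          payload = base
        )),
        id = sprintf("opp%s_p%03d", base, r)
      )
    })
  } else {
    lapply(seq_along(config$disruption_fractions), function(i) {
      frac <- config$disruption_fractions[i]
      new_construct(
        backbone,
        list(perturbation("random_disruption",
          fraction = frac,
          seed = config$rng_seed + i
        )),
        id = sprintf("rd_f%03d", round(100 * frac))
      )
    })
  }
}

#' Assign unique barcodes to a construct list
#'
#' Barcodes are drawn deterministically (given `config$rng_seed`) from a
#' single-check-digit code over the 4-letter alphabet: the last base is the
#' modular checksum of the first seven, which guarantees a pairwise Hamming
#' distance of at least 2 between any two distinct barcodes.
#'
#' @param constructs List of `adar_construct`.
#' @param config A [library_config()].
#' @return The construct list with `barcode` and `full_sequence` filled in.
#' @export
assign_barcodes <- function(constructs, config = library_config()) {
  n <- length(constructs)
  bl <- config$barcode_length
  mh <- config$min_barcode_hamming
  if (any(vapply(constructs, function(x) !is.na(x$barcode), logical(1)))) {
    stop("some constructs already carry barcodes; refusing duplicate request")
  }
  codes <- generate_barcodes(n, bl, mh, config$rng_seed)
  for (i in seq_len(n)) {
    constructs[[i]]$barcode <- codes[i]
    constructs[[i]]$full_sequence <- paste0(
      constructs[[i]]$upper_arm, constructs[[i]]$loop,
      constructs[[i]]$lower_arm, codes[i]
    )
  }
  constructs
}

#' Generate a set of mutually distant barcodes
#'
#' @param n Number of barcodes.
#' @param length Barcode length (default 8).
#' @param min_hamming Required minimum pairwise Hamming distance.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, length = 8L, min_hamming = 2L, seed = 1L) {
  if (n < 1L) stop("need at least one barcode")
  if (n > 4^length) {
    stop(sprintf("cannot draw %d distinct barcodes of length %d", n, length))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old())
  if (min_hamming <= 1L) {
    idx <- sample.int(4^length, n) - 1
    return(vapply(idx, index_to_barcode, character(1), length = length))
  }
  if (min_hamming == 2L) {
    if (n > 4^(length - 1L)) {
      stop(sprintf(
        "cannot draw %d barcodes of length %d at Hamming distance >= 2",
        n, length
      ))
    }
    idx <- sample.int(4^(length - 1L), n) - 1
    return(vapply(idx, function(i) {
      digits <- index_to_digits(i, length - 1L)
      check <- (-sum(digits)) %% 4
      paste(DNA_BASES[c(digits, check) + 1L], collapse = "")
    }, character(1)))
  }
  ## min_hamming > 2: greedy rejection sampling
  accepted <- matrix(integer(0), nrow = 0, ncol = length)
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n) {
      stop("barcode constraint infeasible for requested count")
    }
    cand <- sample.int(4L, length, replace = TRUE)
    if (nrow(accepted) == 0L ||
      all(rowSums(accepted != matrix(cand, nrow(accepted), length,
        byrow = TRUE
      )) >= min_hamming)) {
      accepted <- rbind(accepted, cand)
      out <- c(out, paste(DNA_BASES[cand], collapse = ""))
    }
  }
  out
}

index_to_digits <- function(i, k) {
  digits <- integer(k)
  for (j in seq_len(k)) {
    digits[j] <- i %% 4
    i <- i %/% 4
  }
  digits
}

index_to_barcode <- function(i, length) {
  paste(DNA_BASES[index_to_digits(i, length) + 1L], collapse = "")
}

#' Pairwise Hamming distances of equal-length strings
#'
#' @param codes Character vector.
#' @return Integer matrix of pairwise distances.
#' @export
barcode_hamming <- function(codes) {
  m <- do.call(rbind, strsplit(codes, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n)) {
    d[i, ] <- rowSums(m != matrix(m[i, ], n, ncol(m), byrow = TRUE))
  }
  d
}

## -- disruption geometry ----------------------------------------------------

## Signed-distance convention: distance = (adenosine register) - (disruption
## center register) on the adenosine's own strand; negative means the
## adenosine lies 5' (upstream) of the disruption. Even-length disruption
## centers round toward the 5' side of the strand being measured.
disruption_centers <- function(construct, arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  ls0 <- construct$stem_length
  out <- list()
  for (p in construct$perturbations) {
    if (p$kind == "none") next
    if (p$kind %in% c("mismatch", "opposite_base")) {
      regs <- p$registers
      k <- length(regs)
      r0 <- min(regs)
      centers <- if (arm == "upper") {
        r0 + (k - 1L) %/% 2L
      } else {
        (ls0 - 1L - max(regs)) + (k - 1L) %/% 2L
      }
      opp <- p$opposite
      center_reg <- if (arm == "upper") centers else ls0 - 1L - centers
      out[[length(out) + 1L]] <- data.frame(
        center = centers,
        opposite = as.character(opp[as.character(center_reg)]),
        stringsAsFactors = FALSE
      )
    } else if (p$kind == "bulge") {
      centers <- if (arm == "upper") p$position else ls0 - p$position
      out[[length(out) + 1L]] <- data.frame(
        center = centers, opposite = NA_character_,
        stringsAsFactors = FALSE
      )
    } else if (p$kind == "random_disruption") {
      regs <- p$registers
      centers <- if (arm == "upper") regs else ls0 - 1L - regs
      out[[length(out) + 1L]] <- data.frame(
        center = centers,
        opposite = as.character(p$opposite[as.character(regs)]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(center = integer(0), opposite = character(0)))
  }
  do.call(rbind, out)
}

## The sequence of the arm actually read out
arm_sequence <- function(construct, arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  if (arm == "upper") construct$upper_arm else construct$lower_arm
}

## Adenosine positions on the arm's own strand (0-based string indices,
## which coincide with duplex registers on the upper arm)
arm_adenosines <- function(construct, arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  if (arm == "upper") construct$a_pos_upper else construct$a_pos_lower
}
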