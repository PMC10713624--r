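#' Sequencing simulation configuration
#'
#' @param coverage_per_barcode Mean reads per construct (Poisson), default
#'   4000 as in the screens.
#' @param sequencing_error_rate Per-base substitution error rate (uniform),
#'   in `[0, 0.1]`.
#' @param read_length Length of each mate.
#' @param rng_seed Seed governing all random draws.
#' @param arm Which arm is amplified and sequenced (`"upper"` or
#'   `"lower"`).
#' @return A `simulation_config`.
#' @export
simulation_config <- function(coverage_per_barcode = 4000,
                              sequencing_error_rate = 0.001,
                              read_length = 100L,
                              rng_seed = 1L,
                              arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  stopifnot(
    coverage_per_barcode >= 1,
    sequencing_error_rate >= 0, sequencing_error_rate <= 0.1,
    read_length >= 30
  )
  structure(
    list(
      coverage_per_barcode = coverage_per_barcode,
      sequencing_error_rate = sequencing_error_rate,
      read_length = as.integer(read_length),
      rng_seed = as.integer(rng_seed),
      arm = arm
    ),
    class = "simulation_config"
  )
}

#' Amplicon sequence of a construct
#'
#' The sequenced amplicon is `5'-anchor + arm + barcode + 3'-anchor`; the
#' barcode always sits directly 5' of the 3' anchor, so demultiplexing is
#' placement-agnostic with respect to the arm length.
#'
#' @param construct An `adar_construct` (barcoded).
#' @param arm `"upper"` or `"lower"`.
#' @return Amplicon string.
#' @export
construct_amplicon <- function(construct, arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  if (is.na(construct$barcode)) stop("construct has no barcode")
  paste0(ANCHOR_5P, arm_sequence(construct, arm), construct$barcode, ANCHOR_3P)
}

#' Simulate paired amplicon reads for a barcoded library
#'
#' Per construct, `Poisson(coverage)` molecules are drawn; each adenosine of
#' the sequenced arm is independently converted A->G with its
#' [editing_probability()] (lower-arm editing requires the profile's
#' `symmetric` flag); uniform substitution errors are then applied
#' independently to each mate. Mate 1 reads the amplicon 5' end, mate 2 the
#' reverse complement of its 3' end; quality strings are constant.
#' The output is deterministic for a fixed `rng_seed`.
#'
#' @param library List of barcoded `adar_construct`s.
#' @param profile An [enzyme_profile()].
#' @param sim A [simulation_config()].
#' @param out_dir Directory receiving `reads_R1.fastq` / `reads_R2.fastq`.
#' @return Invisibly, a list with `r1`, `r2` (paths), `ground_truth`
#'   (data.frame: construct, arm, position, true_prob) and `n_reads`.
#' @export
simulate_library_reads <- function(library, profile, sim = simulation_config(),
                                   out_dir = tempfile("simreads")) {
  if (!length(library)) stop("empty library")
  if (any(vapply(library, function(x) is.na(x$barcode), logical(1)))) {
    stop("library must be barcoded before simulation")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(sim$rng_seed)
  rl <- sim$read_length
  err <- sim$sequencing_error_rate
  r1_all <- vector("list", length(library))
  r2_all <- vector("list", length(library))
  gt <- vector("list", length(library))
  for (ci in seq_along(library)) {
    con <- library[[ci]]
    amp <- construct_amplicon(con, sim$arm)
    la <- nchar(amp)
    if (la < rl) stop("amplicon shorter than read length for ", con$id)
    a_arm <- arm_adenosines(con, sim$arm)
    p <- if (length(a_arm)) {
      editing_probability(con, profile, a_arm, arm = sim$arm)
    } else {
      numeric(0)
    }
    a_amp <- a_arm + nchar(ANCHOR_5P) + 1L # 1-based columns in the amplicon
    n <- stats::rpois(1L, sim$coverage_per_barcode)
    gt[[ci]] <- data.frame(
      construct = con$id, arm = sim$arm, position = a_arm,
      true_prob = p, stringsAsFactors = FALSE
    )
    if (n == 0L) {
      r1_all[[ci]] <- character(0)
      r2_all[[ci]] <- character(0)
      next
    }
    mol <- matrix(seq_chars(amp), nrow = n, ncol = la, byrow = TRUE)
    for (j in seq_along(a_amp)) {
      hit <- stats::runif(n) < p[j]
      if (any(hit)) mol[hit, a_amp[j]] <- "G"
    }
    r1m <- mol[, seq_len(rl), drop = FALSE]
    r2m <- mol[, (la - rl + 1L):la, drop = FALSE]
    r1_all[[ci]] <- collapse_rows(apply_seq_errors(r1m, err))
    r2_all[[ci]] <- revcomp(collapse_rows(apply_seq_errors(r2m, err)))
  }
  r1 <- unlist(r1_all)
  r2 <- unlist(r2_all)
  ord <- sample.int(length(r1)) # pooled library: shuffle read order
  r1 <- r1[ord]
  r2 <- r2[ord]
  ids <- sprintf("sim_%07d", seq_along(r1))
  r1_path <- file.path(out_dir, "reads_R1.fastq")
  r2_path <- file.path(out_dir, "reads_R2.fastq")
  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)
  invisible(list(
    r1 = r1_path, r2 = r2_path,
    ground_truth = do.call(rbind, gt),
    n_reads = length(r1),
    profile = profile$name, arm = sim$arm
  ))
}

## uniform substitution errors on a character matrix of reads
apply_seq_errors <- function(m, rate) {
  if (rate <= 0) {
    return(m)
  }
  k <- stats::rbinom(1L, length(m), rate)
  if (k == 0L) {
    return(m)
  }
  idx <- sample.int(length(m), k)
  cur <- m[idx]
  sub <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  m[idx] <- sub
  m
}

collapse_rows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  out <- character(4L * length(ids))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file as a character vector
#'
#' @param path FASTQ path.
#' @return Character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write simulation ground truth to TSV
#'
#' Records the true per-position editing probability of each simulated
#' construct, plus the simulating profile's induction offset (`true_offset`)
#' so downstream offset calls can be checked against it.
#'
#' @param gt Ground-truth data.frame from [simulate_library_reads()].
#' @param path Output TSV path.
#' @param true_offset Signed induction offset used by the simulation.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(gt, path, true_offset = NA_integer_) {
  gt$true_offset <- true_offset
  utils::write.table(gt, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a ground-truth TSV
#'
#' @param path TSV path.
#' @param manifest_ids Optional construct ids to validate against.
#' @return Data.frame with columns construct, arm, position, true_prob,
#'   true_offset.
#' @export
read_ground_truth <- function(path, manifest_ids = NULL) {
  gt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(gt$true_prob < 0 | gt$true_prob > 1)) {
    stop("ground truth contains probabilities outside [0, 1]")
  }
  if (!is.null(manifest_ids)) {
    missing <- setdiff(unique(gt$construct), manifest_ids)
    if (length(missing)) {
      stop(
        "ground truth references constructs absent from the manifest: ",
        paste(missing, collapse = ", ")
      )
    }
  }
  gt
}
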