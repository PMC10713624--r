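#' Merge paired reads and apply the screen's read filters
#'
#' Mate pairs are merged by exact-overlap truncation: for each candidate
#' amplicon length in the library, the suffix of mate 1 must equal the
#' corresponding prefix of the reverse-complemented mate 2 over at least
#' `min_overlap` nt; pairs with no exact overlap are dropped. Merged reads
#' are then filtered in the order the screen applied them: (i) wrong 5'/3'
#' anchor sequences, (ii) barcode not present in the manifest (exact
#' match), (iii) length inconsistent with the barcode's construct, (iv)
#' disagreement with the construct reference at any non-adenosine position,
#' (v) a base other than A/G at an adenosine position. Every dropped pair
#' is tallied by reason.
#'
#' @param r1,r2 FASTQ paths or character vectors of mate sequences.
#' @param library List of barcoded `adar_construct` (the manifest).
#' @param min_overlap Minimum exact overlap (nt) for merging.
#' @param arm Arm that was sequenced.
#' @return A list of class `merged_reads`: `reads` (data.frame with
#'   `construct` and `seq`), `report` (named drop tallies plus
#'   `reads_in`/`reads_kept`), `per_construct` (per-barcode conservation
#'   table).
#' @export
merge_and_filter_reads <- function(r1, r2, library, min_overlap = 15L,
                                   arm = c("upper", "lower")) {
  arm <- match.arg(arm)
  if (length(r1) == 1L && file.exists(r1)) r1 <- read_fastq(r1)
  if (length(r2) == 1L && file.exists(r2)) r2 <- read_fastq(r2)
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  n_in <- length(r1)
  amp_by_id <- vapply(library, construct_amplicon, character(1), arm = arm)
  names(amp_by_id) <- vapply(library, `[[`, character(1), "id")
  amp_lens <- sort(unique(nchar(amp_by_id)))
  n1 <- nchar(r1)
  n2 <- nchar(r2)
  if (any(n1 + n2 - max(amp_lens) < min_overlap)) {
    stop("reads too short for the required overlap")
  }
  rc2 <- revcomp(r2)
  merged <- rep(NA_character_, n_in)
  for (la in amp_lens) {
    todo <- which(is.na(merged) & n1 + n2 >= la + min_overlap & pmax(n1, n2) <= la)
    if (!length(todo)) next
    ov_start <- la - n2[todo] + 1L
    ok <- substr(r1[todo], ov_start, n1[todo]) ==
      substr(rc2[todo], 1L, n1[todo] - ov_start + 1L)
    hit <- todo[ok]
    if (length(hit)) {
      merged[hit] <- paste0(
        substr(r1[hit], 1L, la - n2[hit]), rc2[hit]
      )
    }
  }
  report <- c(
    merge_failed = 0L, bad_anchor = 0L, unknown_barcode = 0L,
    length_mismatch = 0L, ref_mismatch = 0L, non_AG_at_A = 0L
  )
  report["merge_failed"] <- sum(is.na(merged))
  keep <- !is.na(merged)
  merged <- merged[keep]
  ml <- nchar(merged)
  la5 <- nchar(ANCHOR_5P)
  la3 <- nchar(ANCHOR_3P)
  anchor_ok <- substr(merged, 1L, la5) == ANCHOR_5P &
    substr(merged, ml - la3 + 1L, ml) == ANCHOR_3P
  report["bad_anchor"] <- sum(!anchor_ok)
  merged <- merged[anchor_ok]
  ml <- ml[anchor_ok]
  bc_map <- barcode_index(library)
  bl <- nchar(names(bc_map)[1])
  bc <- substr(merged, ml - la3 - bl + 1L, ml - la3)
  cid <- unname(bc_map[bc])
  known <- !is.na(cid)
  report["unknown_barcode"] <- sum(!known)
  merged <- merged[known]
  ml <- ml[known]
  cid <- cid[known]
  len_ok <- ml == nchar(amp_by_id[cid])
  report["length_mismatch"] <- sum(!len_ok)
  merged <- merged[len_ok]
  cid <- cid[len_ok]
  ## per-construct reference comparison
  keep_final <- logical(length(merged))
  assigned <- integer(0)
  per_con <- list()
  for (id in unique(cid)) {
    idx <- which(cid == id)
    ref <- seq_chars(amp_by_id[id])
    m <- do.call(rbind, strsplit(merged[idx], "", fixed = TRUE))
    a_cols <- arm_adenosines(get_construct(library, id), arm) +
      la5 + 1L
    non_a <- setdiff(seq_along(ref), a_cols)
    ref_ok <- rowSums(m[, non_a, drop = FALSE] !=
      matrix(ref[non_a], length(idx), length(non_a), byrow = TRUE)) == 0L
    if (length(a_cols)) {
      ag_mat <- m[, a_cols, drop = FALSE]
      ag_ok <- rowSums(ag_mat != "A" & ag_mat != "G") == 0L
    } else {
      ag_ok <- rep(TRUE, length(idx))
    }
    report["ref_mismatch"] <- report["ref_mismatch"] + sum(!ref_ok)
    report["non_AG_at_A"] <- report["non_AG_at_A"] + sum(ref_ok & !ag_ok)
    keep_final[idx] <- ref_ok & ag_ok
    per_con[[id]] <- data.frame(
      construct = id, reads_assigned = length(idx),
      kept = sum(ref_ok & ag_ok), ref_mismatch = sum(!ref_ok),
      non_AG_at_A = sum(ref_ok & !ag_ok), stringsAsFactors = FALSE
    )
  }
  reads <- data.frame(
    construct = cid[keep_final], seq = merged[keep_final],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      reads = reads,
      report = c(reads_in = n_in, reads_kept = nrow(reads), report),
      per_construct = if (length(per_con)) {
        do.call(rbind, per_con)
      } else {
        data.frame()
      },
      arm = arm
    ),
    class = "merged_reads"
  )
}

get_construct <- function(library, id) {
  ids <- vapply(library, `[[`, character(1), "id")
  hit <- match(id, ids)
  if (is.na(hit)) stop("unknown construct id: ", id)
  library[[hit]]
}

#' @export
print.merged_reads <- function(x, ...) {
  cat("<merged_reads>", x$report["reads_kept"], "/", x$report["reads_in"],
    "reads kept (", x$arm, "arm )\n"
  )
  drops <- x$report[!names(x$report) %in% c("reads_in", "reads_kept")]
  drops <- drops[drops > 0]
  if (length(drops)) {
    cat(
      "  dropped:",
      paste(sprintf("%s=%d", names(drops), drops), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Editing percentage from A/G counts
#'
#' `100 * g / (a + g)` where `a + g > 0`, missing (`NA`) otherwise —
#' positions with zero informative coverage are never reported as 0%.
#'
#' @param a,g Counts of A and G calls (vectorized).
#' @return Editing percentages.
#' @export
#' @examples
#' editing_percent(3, 1) # 25
editing_percent <- function(a, g) {
  ifelse(a + g > 0, 100 * g / (a + g), NA_real_)
}

#' Per-adenosine editing quantification
#'
#' For each adenosine of the sequenced arm, counts A and G calls across the
#' construct's kept reads and computes the editing percentage
#' `100 * G / (A + G)`. Positions with zero coverage are reported missing
#' (`NA`), not zero.
#'
#' @param merged A `merged_reads` object (or a data.frame with `construct`
#'   and `seq`).
#' @param library List of `adar_construct`.
#' @param arm Sequenced arm (taken from `merged` when available).
#' @return Named list of `editing_profile` data.frames (columns `position`,
#'   `a`, `g`, `percent`), one per construct with at least one kept read;
#'   constructs without adenosines yield an empty profile with a warning.
#' @export
quantify_editing <- function(merged, library, arm = NULL) {
  if (inherits(merged, "merged_reads")) {
    if (is.null(arm)) arm <- merged$arm
    reads <- merged$reads
  } else {
    reads <- merged
    if (is.null(arm)) arm <- "upper"
  }
  la5 <- nchar(ANCHOR_5P)
  out <- list()
  for (id in unique(reads$construct)) {
    con <- get_construct(library, id)
    a_pos <- arm_adenosines(con, arm)
    seqs <- reads$seq[reads$construct == id]
    if (!length(a_pos)) {
      warning("construct without adenosines on the ", arm, " arm: ", id)
      prof <- data.frame(
        position = integer(0), a = integer(0),
        g = integer(0), percent = numeric(0)
      )
    } else {
      cols <- a_pos + la5 + 1L
      a_n <- integer(length(cols))
      g_n <- integer(length(cols))
      for (j in seq_along(cols)) {
        b <- substr(seqs, cols[j], cols[j])
        a_n[j] <- sum(b == "A")
        g_n[j] <- sum(b == "G")
      }
      prof <- data.frame(
        position = a_pos, a = a_n, g = g_n,
        percent = editing_percent(a_n, g_n)
      )
    }
    attr(prof, "construct") <- id
    attr(prof, "arm") <- arm
    attr(prof, "reads_used") <- length(seqs)
    class(prof) <- c("editing_profile", "data.frame")
    out[[id]] <- prof
  }
  out
}

#' Per-molecule editing-event counts
#'
#' Counts, for each kept read of a construct, how many adenosine positions
#' were read as G, and summarizes the distribution.
#'
#' @param merged A `merged_reads` object or reads data.frame.
#' @param library List of `adar_construct`.
#' @param construct_id Construct to summarize (default: all).
#' @param arm Sequenced arm.
#' @return A list with `counts` (data.frame construct/edited) and `summary`
#'   (per construct: n, median, q25, q75).
#' @export
per_molecule_distribution <- function(merged, library, construct_id = NULL,
                                      arm = NULL) {
  if (inherits(merged, "merged_reads")) {
    if (is.null(arm)) arm <- merged$arm
    reads <- merged$reads
  } else {
    reads <- merged
    if (is.null(arm)) arm <- "upper"
  }
  if (!is.null(construct_id)) {
    reads <- reads[reads$construct %in% construct_id, , drop = FALSE]
  }
  la5 <- nchar(ANCHOR_5P)
  counts <- lapply(unique(reads$construct), function(id) {
    con <- get_construct(library, id)
    cols <- arm_adenosines(con, arm) + la5 + 1L
    seqs <- reads$seq[reads$construct == id]
    cnt <- integer(length(seqs))
    for (cc in cols) cnt <- cnt + (substr(seqs, cc, cc) == "G")
    data.frame(construct = id, edited = cnt, stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, counts)
  summ <- do.call(rbind, lapply(split(counts$edited, counts$construct), function(v) {
    data.frame(
      n = length(v), median = stats::median(v),
      q25 = unname(stats::quantile(v, 0.25)),
      q75 = unname(stats::quantile(v, 0.75))
    )
  }))
  summ$construct <- rownames(summ)
  rownames(summ) <- NULL
  list(counts = counts, summary = summ[, c("construct", "n", "median", "q25", "q75")])
}

#' Pearson correlation between two editing profiles
#'
#' @param profile_a,profile_b `editing_profile` data.frames sharing
#'   positions.
#' @return List with `r`, `p` (two-sided, t-distribution with n-2 df) and
#'   `n`.
#' @export
replicate_correlation <- function(profile_a, profile_b) {
  m <- merge(profile_a[, c("position", "percent")],
    profile_b[, c("position", "percent")],
    by = "position", suffixes = c("_a", "_b")
  )
  m <- m[!is.na(m$percent_a) & !is.na(m$percent_b), ]
  if (nrow(m) < 3L) stop("need at least 3 shared positions with coverage")
  if (stats::sd(m$percent_a) == 0 || stats::sd(m$percent_b) == 0) {
    stop("zero variance in one of the profiles")
  }
  ct <- stats::cor.test(m$percent_a, m$percent_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
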