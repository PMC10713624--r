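#' Classify secondary-structure elements of a dot-bracket string
#'
#' Assigns each position of a balanced, non-crossing dot-bracket string one
#' of: `stem` (paired), `hairpin_loop` (unpaired inside a pair enclosing no
#' further helix), `bulge` (unpaired on one strand of an interior gap),
#' `internal_loop` (unpaired on both strands), `multiloop` (loop with >= 2
#' emanating helices), `exterior` (outside all pairs). Any non-stem label
#' counts as "open" in the metaplot dichotomy.
#'
#' @param dot_bracket Dot-bracket string (characters `(`, `)`, `.`).
#' @return Character vector of per-position labels, with the 0-based pair
#'   table (`NA` for unpaired) as attribute `pairs`.
#' @export
#' @examples
#' classify_elements("((((....))))")
classify_elements <- function(dot_bracket) {
  chars <- seq_chars(dot_bracket)
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) {
    stop("invalid dot-bracket characters: ", paste(bad, collapse = ", "))
  }
  n <- length(chars)
  pair <- rep(NA_integer_, n)
  parent_open <- rep(NA_integer_, n) # directly enclosing '(' index
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      parent_open[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    } else {
      parent_open[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  labels <- rep(NA_character_, n)
  labels[!is.na(pair)] <- "stem"
  unpaired <- which(is.na(pair))
  labels[unpaired[is.na(parent_open[unpaired])]] <- "exterior"
  ## classify each loop (the region enclosed by one pair) as a whole
  opens <- which(chars == "(")
  for (o in opens) {
    c_ <- pair[o]
    inside <- if (o + 1L <= c_ - 1L) (o + 1L):(c_ - 1L) else integer(0)
    direct <- inside[!is.na(pair[inside]) & chars[inside] == "(" &
      !is.na(parent_open[inside]) & parent_open[inside] == o]
    loop_unpaired <- inside[is.na(pair[inside]) &
      !is.na(parent_open[inside]) & parent_open[inside] == o]
    if (!length(loop_unpaired)) next
    nb <- length(direct)
    lab <- if (nb == 0L) {
      "hairpin_loop"
    } else if (nb >= 2L) {
      "multiloop"
    } else {
      ## one emanating helix: gaps on the 5' and 3' side of it
      h_open <- direct[1]
      h_close <- pair[h_open]
      left <- loop_unpaired[loop_unpaired < h_open]
      right <- loop_unpaired[loop_unpaired > h_close]
      if (length(left) && length(right)) "internal_loop" else "bulge"
    }
    labels[loop_unpaired] <- lab
  }
  attr(labels, "pairs") <- pair - 1L
  labels
}

#' Bundle a structure with its element labels
#'
#' @param id Structure identifier.
#' @param sequence Nucleotide sequence.
#' @param dot_bracket Dot-bracket string of the same length.
#' @return A `structure_record` with per-position `element_labels`.
#' @export
structure_record <- function(id, sequence, dot_bracket) {
  sequence <- normalize_seq(sequence, "sequence")
  if (nchar(sequence) != nchar(dot_bracket)) {
    stop("sequence and dot-bracket lengths differ for ", id)
  }
  structure(
    list(
      id = id, sequence = sequence, dot_bracket = dot_bracket,
      element_labels = classify_elements(dot_bracket)
    ),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  open <- mean(x$element_labels != "stem")
  cat(sprintf(
    "<structure_record '%s'> %d nt, %.0f%% open\n",
    x$id, nchar(x$sequence), 100 * open
  ))
  invisible(x)
}

#' Read Vienna-style structure files
#'
#' Parses records of the form `>id` / sequence line / dot-bracket line.
#'
#' @param path File path.
#' @return Named list of `structure_record`.
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr) || any(diff(hdr) != 3L) || length(lines) != max(hdr) + 2L) {
    stop("malformed structure file: expected >id / sequence / dot-bracket records")
  }
  recs <- lapply(hdr, function(i) {
    structure_record(sub("^>\\s*", "", lines[i]), lines[i + 1L], lines[i + 2L])
  })
  stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
}

#' Write Vienna-style structure files
#'
#' @param structures List of `structure_record`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_structures <- function(structures, path) {
  out <- unlist(lapply(structures, function(s) {
    c(paste0(">", s$id), s$sequence, s$dot_bracket)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Select analyzable inverted-repeat element pairs
#'
#' Applies the endogenous-target filters: both elements in UTRs, opposite
#' orientation, within `max_separation` nt of each other (gap between
#' them), and no third element inside the window spanning the pair.
#'
#' @param annotations A `GRanges` (with mcol `region_class`) or a
#'   data.frame with columns `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `region_class`.
#' @param max_separation Maximum gap between paired elements (nt).
#' @return Data.frame of selected pairs (contig, first/second indices and
#'   coordinates), with rejected candidates and their reasons in attribute
#'   `rejected`.
#' @export
select_element_pairs <- function(annotations, max_separation = 2000L) {
  if (inherits(annotations, "GRanges")) {
    df <- data.frame(
      contig = as.character(GenomicRanges::seqnames(annotations)),
      start = GenomicRanges::start(annotations) - 1L,
      end = GenomicRanges::end(annotations),
      strand = as.character(GenomicRanges::strand(annotations)),
      region_class = annotations$region_class,
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(annotations, stringsAsFactors = FALSE)
  }
  if (any(df$start >= df$end)) stop("malformed intervals: start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$contig, df$start), ]
  gr <- GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start + 1L, df$end),
    strand = df$strand
  )
  selected <- list()
  rejected <- list()
  idx <- seq_len(nrow(df))
  for (i in idx) {
    for (j in idx[idx > i]) {
      if (df$contig[j] != df$contig[i]) next
      gap <- df$start[j] - df$end[i]
      if (gap > 10L * max_separation) break
      reason <- NULL
      if (gap > max_separation) {
        reason <- "separation"
      } else if (!(df$region_class[i] == "UTR" && df$region_class[j] == "UTR")) {
        reason <- "not_utr"
      } else if (df$strand[i] == df$strand[j]) {
        reason <- "same_orientation"
      } else {
        window <- GenomicRanges::GRanges(
          df$contig[i],
          IRanges::IRanges(df$start[i] + 1L, df$end[j])
        )
        inside <- GenomicRanges::countOverlaps(window, gr) # includes i and j
        if (inside > 2L) reason <- "extra_element"
      }
      rec <- data.frame(
        contig = df$contig[i], first = i, second = j,
        first_start = df$start[i], first_end = df$end[i],
        second_start = df$start[j], second_end = df$end[j],
        gap = gap, stringsAsFactors = FALSE
      )
      if (is.null(reason)) {
        selected[[length(selected) + 1L]] <- rec
      } else {
        rec$reason <- reason
        rejected[[length(rejected) + 1L]] <- rec
      }
    }
  }
  out <- if (length(selected)) {
    do.call(rbind, selected)
  } else {
    data.frame()
  }
  attr(out, "rejected") <- if (length(rejected)) {
    do.call(rbind, rejected)
  } else {
    data.frame()
  }
  out
}

#' Open/closed annotation of the window around a site
#'
#' Annotates each offset in `-half_width..+half_width` around a site
#' (offset 0 = the site itself; + = 3' on the site's strand) as `"open"`
#' (non-stem), `"closed"` (stem) or `NA` (outside the structure).
#'
#' @param structure A `structure_record`.
#' @param site 0-based position within the structure.
#' @param half_width Window half-width (default 40, the 80-nt window).
#' @return Named character vector over offsets.
#' @export
openness_window <- function(structure, site, half_width = 40L) {
  n <- nchar(structure$sequence)
  if (site < 0L || site >= n) stop("site outside the structure")
  offs <- (-half_width):half_width
  pos <- site + offs
  out <- rep(NA_character_, length(offs))
  inb <- pos >= 0L & pos < n
  lab <- structure$element_labels[pos[inb] + 1L]
  out[inb] <- ifelse(lab == "stem", "closed", "open")
  stats::setNames(out, offs)
}

#' Open-versus-closed differential editing metaplot
#'
#' For each offset in the 80-nt window centered on qualifying editing
#' sites (editing above `min_editing` percent), splits the sites into
#' those with an open versus a closed structure at that offset and
#' computes the difference in mean editing levels, with a two-sided
#' Welch t-test and Benjamini-Hochberg adjustment across offsets. Offsets
#' where either group is smaller than `min_group` are reported untested.
#'
#' @param sites Data.frame with columns `structure_id`, `position`
#'   (0-based), `editing_level` (percent).
#' @param structures Named list of `structure_record`.
#' @param min_editing Inclusion threshold on editing level (percent).
#' @param min_group Minimum group size for testing.
#' @param half_width Window half-width.
#' @return A `metaplot_result` data.frame: offset, n_open, n_closed,
#'   n_missing, mean_open, mean_closed, difference, t, p, q, status.
#' @export
metaplot_differential <- function(sites, structures, min_editing = 3.0,
                                  min_group = 5L, half_width = 40L) {
  sites <- sites[!is.na(sites$editing_level) &
    sites$editing_level > min_editing, , drop = FALSE]
  if (!nrow(sites)) stop("no sites above the editing threshold")
  missing_ids <- setdiff(unique(sites$structure_id), names(structures))
  if (length(missing_ids)) {
    stop(
      "sites reference unknown structures: ",
      paste(missing_ids, collapse = ", ")
    )
  }
  wins <- t(vapply(
    seq_len(nrow(sites)),
    function(i) {
      openness_window(
        structures[[sites$structure_id[i]]],
        sites$position[i], half_width
      )
    },
    character(2L * half_width + 1L)
  ))
  offs <- (-half_width):half_width
  lv <- sites$editing_level
  rows <- lapply(seq_along(offs), function(k) {
    w <- wins[, k]
    open <- lv[!is.na(w) & w == "open"]
    closed <- lv[!is.na(w) & w == "closed"]
    res <- data.frame(
      offset = offs[k],
      n_open = length(open), n_closed = length(closed),
      n_missing = sum(is.na(w)),
      mean_open = if (length(open)) mean(open) else NA_real_,
      mean_closed = if (length(closed)) mean(closed) else NA_real_,
      difference = NA_real_, t = NA_real_, p = NA_real_,
      status = "untestable", stringsAsFactors = FALSE
    )
    if (length(open) && length(closed)) {
      res$difference <- res$mean_open - res$mean_closed
    }
    if (length(open) >= min_group && length(closed) >= min_group &&
      (stats::sd(open) > 0 || stats::sd(closed) > 0)) {
      tt <- stats::t.test(open, closed) # Welch, two-sided
      res$t <- unname(tt$statistic)
      res$p <- tt$p.value
      res$status <- "ok"
    }
    res
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- out$status == "ok"
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  attr(out, "n_sites") <- nrow(sites)
  class(out) <- c("metaplot_result", "data.frame")
  out
}
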