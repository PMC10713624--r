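## Library files: a FASTA of full construct sequences (hairpin + barcode)
## and a TSV manifest carrying the backbone, per-construct barcode,
## perturbation list and adenosine positions; the pair round-trips
## losslessly through read_library().

serialize_perturbations <- function(perturbations) {
  if (!length(perturbations)) {
    return("none")
  }
  paste(vapply(perturbations, function(p) {
    paste(p$kind, p$position, p$length,
      ifelse(is.na(p$payload), ".", p$payload),
      ifelse(is.na(p$fraction), ".", format(p$fraction)),
      ifelse(is.na(p$seed), ".", p$seed),
      sep = ":"
    )
  }, character(1)), collapse = ";")
}

parse_perturbations <- function(x) {
  if (identical(x, "none")) {
    return(list())
  }
  lapply(strsplit(x, ";", fixed = TRUE)[[1]], function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(f) != 6L) stop("malformed perturbation field: ", s)
    perturbation(
      kind = f[1],
      position = suppressWarnings(as.integer(f[2])),
      length = suppressWarnings(as.integer(f[3])),
      payload = ifelse(f[4] == ".", NA_character_, f[4]),
      fraction = ifelse(f[5] == ".", NA_real_, as.numeric(f[5])),
      seed = ifelse(f[6] == ".", NA_integer_, as.integer(f[6]))
    )
  })
}

#' Write a designed library to disk
#'
#' Emits `library.fasta` (full sequences, 80-column wrapped) and
#' `manifest.tsv` (id, barcode, perturbations, arm-local and full-sequence
#' adenosine coordinates, with the backbone recorded in header comments).
#'
#' @param constructs Barcoded list of `adar_construct`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_library <- function(constructs, dir) {
  if (any(vapply(constructs, function(x) is.na(x$barcode), logical(1)))) {
    stop("constructs must be barcoded before writing")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "library.fasta")
  manifest <- file.path(dir, "manifest.tsv")
  seqs <- DNAStringSet(vapply(constructs, `[[`, character(1), "full_sequence"))
  names(seqs) <- vapply(constructs, `[[`, character(1), "id")
  writeXStringSet(seqs, fasta, width = 80L)
  b <- constructs[[1]]
  header <- c(
    sprintf("# backbone=%s", b$backbone_name),
    sprintf("# upper_arm=%s", b$upper_arm),
    sprintf("# loop=%s", b$loop)
  )
  df <- data.frame(
    id = vapply(constructs, `[[`, character(1), "id"),
    barcode = vapply(constructs, `[[`, character(1), "barcode"),
    perturbations = vapply(
      constructs, function(x) serialize_perturbations(x$perturbations),
      character(1)
    ),
    a_pos_upper = vapply(
      constructs, function(x) paste(x$a_pos_upper, collapse = ","),
      character(1)
    ),
    a_pos_lower = vapply(
      constructs, function(x) paste(x$a_pos_lower, collapse = ","),
      character(1)
    ),
    a_pos_upper_full = vapply(
      constructs, function(x) paste(x$a_pos_upper, collapse = ","),
      character(1)
    ),
    a_pos_lower_full = vapply(
      constructs,
      function(x) {
        off <- nchar(x$upper_arm) + nchar(x$loop)
        paste(x$a_pos_lower + off, collapse = ",")
      },
      character(1)
    ),
    stringsAsFactors = FALSE
  )
  con <- file(manifest, "w")
  writeLines(header, con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  close(con)
  invisible(list(fasta = fasta, manifest = manifest))
}

#' Read a designed library back from disk
#'
#' Reconstructs the construct list from the manifest and verifies it
#' against the FASTA: every manifest row must have a FASTA record whose
#' sequence matches the reconstruction (and vice versa), and barcodes must
#' have the designed length.
#'
#' @param dir Directory written by [write_library()].
#' @param barcode_length Expected barcode length.
#' @return List of `adar_construct`.
#' @export
read_library <- function(dir, barcode_length = 8L) {
  fasta <- file.path(dir, "library.fasta")
  manifest <- file.path(dir, "manifest.tsv")
  lines <- readLines(manifest)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop("manifest missing header field: ", key)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  backbone <- build_backbone(
    get_field("upper_arm"), get_field("loop"),
    name = get_field("backbone")
  )
  df <- utils::read.delim(
    textConnection(lines[!grepl("^#", lines)]),
    stringsAsFactors = FALSE, colClasses = "character"
  )
  bad_bc <- nchar(df$barcode) != barcode_length
  if (any(bad_bc)) {
    stop(
      "manifest barcodes with length != ", barcode_length, ": ",
      paste(df$id[bad_bc], collapse = ", ")
    )
  }
  seqs <- readDNAStringSet(fasta)
  fa <- stats::setNames(as.character(seqs), names(seqs))
  extra <- setdiff(names(fa), df$id)
  if (length(extra)) {
    stop(
      "FASTA records absent from the manifest: ",
      paste(extra, collapse = ", ")
    )
  }
  constructs <- lapply(seq_len(nrow(df)), function(i) {
    con <- new_construct(
      backbone, parse_perturbations(df$perturbations[i]),
      id = df$id[i], barcode = df$barcode[i]
    )
    if (!df$id[i] %in% names(fa)) {
      stop("manifest id absent from FASTA: ", df$id[i])
    }
    if (!identical(unname(fa[df$id[i]]), con$full_sequence)) {
      stop("FASTA/manifest sequence mismatch for id: ", df$id[i])
    }
    con
  })
  constructs
}

#' Look up constructs by barcode
#'
#' @param library List of `adar_construct`.
#' @return Named character vector mapping barcode -> construct id.
#' @export
barcode_index <- function(library) {
  stats::setNames(
    vapply(library, `[[`, character(1), "id"),
    vapply(library, `[[`, character(1), "barcode")
  )
}
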