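## 200-nt target with an A at the center and controllable neighbours
make_target <- function(minus1 = "G", seed = 14L, extra_a_at = integer(0)) {
  set.seed(seed)
  chars <- sample(c("C", "G", "T"), 200, replace = TRUE) # A-free background
  chars[101] <- "A" # target A, 0-based index 100
  chars[100] <- minus1
  chars[extra_a_at + 1L] <- "A"
  paste(chars, collapse = "")
}

## re-anneal the guide to the 151-nt window in silico and list mismatched
## duplex registers (relative to the target A)
reannealed_mismatches <- function(design) {
  win <- strsplit(design$window, "")[[1]]
  guide_rev <- rev(strsplit(design$guide_sequence, "")[[1]])
  which(guide_rev != chartr("ACGT", "TGCA", win)) - 1L - design$target_a_index
}

test_that("the positive-control guide is 151 nt with a single central A-C", {
  g <- design_guide(make_target(), 100, "positive_control")
  expect_equal(nchar(g$guide_sequence), 151L)
  expect_equal(g$target_a_index, 75L)
  expect_equal(reannealed_mismatches(g), 0L)
  expect_equal(nrow(g$engineered_mismatches), 1L)
  ## the base opposite the A is C
  expect_equal(
    substr(g$guide_sequence, 151 - 75, 151 - 75), "C"
  )
})

test_that("offset guides place their disruption at the stated duplex distance", {
  g26 <- design_guide(make_target(), 100, "adar2_offset")
  mm <- reannealed_mismatches(g26)
  expect_setequal(mm, c(0L, 26L, 27L, 28L))
  expect_equal(min(setdiff(mm, 0L)), 26L) # near edge at 26 bp
  expect_equal(nrow(g26$engineered_mismatches), 4L)

  g27 <- design_guide(make_target(), 100, "adar2_offset", offset_distance = 27)
  expect_setequal(reannealed_mismatches(g27), c(0L, 27L, 28L, 29L))

  g35 <- design_guide(make_target(), 100, "adar1_offset")
  expect_setequal(reannealed_mismatches(g35), c(0L, 35L, 36L, 37L, 38L))
  expect_equal(nrow(g35$engineered_mismatches), 5L)

  g3 <- design_guide(make_target(), 100, "central_3nt")
  expect_setequal(reannealed_mismatches(g3), c(-1L, 0L, 1L))
  expect_equal(nrow(g3$engineered_mismatches), 3L)

  expect_error(
    design_guide(make_target(), 100, "adar2_offset", offset_distance = 74),
    "outside the 75-nt flank"
  )
})

test_that("-1 guide variants require and exploit an upstream G", {
  ga <- design_guide(make_target(minus1 = "G"), 100, "minus1_GA")
  mm <- ga$engineered_mismatches
  expect_true(all(c(-1L, 0L) %in% mm$target_offset))
  expect_equal(mm$guide_base[mm$target_offset == -1L], "A")
  gg <- design_guide(make_target(minus1 = "G"), 100, "minus1_GG")
  expect_equal(gg$engineered_mismatches$guide_base[
    gg$engineered_mismatches$target_offset == -1L
  ], "G")
  expect_error(
    design_guide(make_target(minus1 = "C"), 100, "minus1_GA"),
    "no upstream G"
  )
})

test_that("design validation catches bad targets and the empty mode", {
  expect_error(design_guide(make_target(), 99, "positive_control"), "not A")
  expect_error(
    design_guide(substr(make_target(), 1, 120), 100, "positive_control"),
    "window too short"
  )
  e <- design_guide(make_target(), 100, "empty")
  expect_true(is.na(e$guide_sequence))
  expect_equal(nrow(e$engineered_mismatches), 0L)
})

test_that("the duplex register map is an involutive bijection", {
  g <- design_guide(make_target(), 100, "positive_control")
  m <- duplex_register_map(g)
  expect_equal(m$guide_position[m$target_position == 75], 75)
  expect_equal(m$guide_position[m$target_position == 75 - 26], 75 + 26)
  expect_equal(sort(m$guide_position), 0:150)
  ## mapping twice returns the original coordinate
  twice <- duplex_register_map(g, m$guide_position)
  expect_equal(twice$guide_position, m$target_position)
  expect_equal(m$distance, m$target_position - 75L)
  expect_error(duplex_register_map(g, 151), "outside")
})

test_that("off-target prediction flags induction-offset adenosines and depleted ones", {
  ## non-target adenosines at +26 and -26 around the central mismatch
  tw <- make_target(extra_a_at = c(100L - 26L, 100L + 26L))
  pc <- design_guide(tw, 100, "positive_control")
  prof <- adar_profile("adar2")
  ot <- predict_offtargets(pc, prof)
  expect_true(all(c(-26L, 26L) %in% ot$distance))
  expect_equal(ot$mechanism[ot$distance == -26L], "upstream_induction")
  expect_equal(ot$mechanism[ot$distance == 26L], "mirror_induction")
  expect_true(all(ot$predicted))

  ## a disruption covering +26..+28 depletes the +26 adenosine instead
  g26 <- design_guide(tw, 100, "adar2_offset")
  ot26 <- predict_offtargets(g26, prof)
  expect_equal(ot26$mechanism[ot26$distance == 26L], "depleted")

  ## no non-target adenosines -> no calls
  expect_equal(nrow(predict_offtargets(
    design_guide(make_target(), 100, "positive_control"), prof
  )), 0L)
})

test_that("amplicon quantification applies the 2% off-target threshold", {
  ref <- make_target(extra_a_at = c(60L, 140L))
  refc <- strsplit(ref, "")[[1]]
  n_reads <- 1000L
  reads <- rep(ref, n_reads)
  flip <- function(reads, pos0, k) {
    ## set the first k reads to G at 0-based pos0
    substr(reads[seq_len(k)], pos0 + 1L, pos0 + 1L) <- "G"
    reads
  }
  reads <- flip(reads, 100L, 300L) # target: 30%
  reads <- flip(reads, 60L, 61L) # off-target: 6.1%
  reads <- flip(reads, 140L, 10L) # below threshold: 1.0%
  qa <- quantify_amplicon(reads, ref, 100L)
  tab <- qa$table
  expect_equal(tab$percent[tab$position == 100], 30)
  expect_equal(tab$percent[tab$position == 60], 6.1)
  expect_equal(tab$percent[tab$position == 140], 1.0)
  expect_equal(qa$offtargets$position, 60L)

  ## unedited reads: zero everywhere, no off-targets
  qa0 <- quantify_amplicon(rep(ref, 10), ref, 100L)
  expect_true(all(qa0$table$percent == 0))
  expect_equal(nrow(qa0$offtargets), 0L)

  expect_error(quantify_amplicon(character(0), ref, 100L), "no reads")
  expect_error(quantify_amplicon(rep(ref, 2), ref, 99L), "not an A")
})

test_that("offset guides out-edit the positive control under their matching enzyme", {
  tw <- make_target()
  designs <- list(
    positive_control = design_guide(tw, 100, "positive_control"),
    adar2_offset = design_guide(tw, 100, "adar2_offset"),
    adar1_offset = design_guide(tw, 100, "adar1_offset")
  )
  bcs <- generate_barcodes(3, seed = 50)
  lib <- Map(function(d, bc) guide_duplex_construct(d, id = d$mode, barcode = bc),
    designs, bcs
  )
  names(lib) <- NULL
  target_percent <- function(profile_name, seed) {
    sim <- simulate_library_reads(
      lib, adar_profile(profile_name),
      simulation_config(coverage_per_barcode = 800, rng_seed = seed),
      withr::local_tempdir()
    )
    profs <- quantify_editing(merge_and_filter_reads(sim$r1, sim$r2, lib), lib)
    vapply(profs, function(p) p$percent[p$position == 75], numeric(1))
  }
  under_adar2 <- target_percent("adar2", 61)
  expect_gt(under_adar2[["adar2_offset"]], under_adar2[["positive_control"]])
  under_adar1 <- target_percent("adar1", 62)
  expect_gt(under_adar1[["adar1_offset"]], under_adar1[["positive_control"]])
})
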