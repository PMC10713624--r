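test_that("editing probability combines baseline, induction and suppression", {
  bb <- small_backbone(stem = 80L)
  perfect <- reference_construct(bb)
  prof <- plain_profile(baseline = 0.3)
  a_pos <- perfect$a_pos_upper

  ## perfect duplex, neutral context: baseline everywhere
  expect_equal(
    editing_probability(perfect, prof, a_pos),
    rep(0.3, length(a_pos))
  )

  ## an adenosine 26 nt upstream of a mismatch is boosted by the fold
  target <- a_pos[a_pos + 26 <= 77 & a_pos + 26 >= 2][1]
  con <- new_construct(bb,
    list(perturbation("mismatch", position = target + 25L, length = 3L)),
    id = "mm"
  )
  expect_equal(editing_probability(con, prof, target), 0.3 * 1.4)

  ## an adenosine at the disrupted register itself is fully suppressed
  prof0 <- plain_profile(baseline = 0.3, suppression = {
    s <- default_suppression("0")
    s
  })
  con0 <- new_construct(bb,
    list(perturbation("mismatch", position = target, length = 1L)),
    id = "mm0"
  )
  expect_equal(editing_probability(con0, prof0, target), 0)

  expect_error(
    editing_probability(perfect, prof, setdiff(0:79, a_pos)[1]),
    "not adenosines"
  )
})

test_that("an adenosine opposite C is boosted, not suppressed", {
  bb <- small_backbone(stem = 40L)
  a <- bb |> (\(b) adenosine_positions(b$upper_arm))()
  con <- new_construct(bb,
    list(perturbation("opposite_base", position = a[3], length = 1L, payload = "C")),
    id = "ac"
  )
  prof <- plain_profile(baseline = 0.4)
  expect_equal(editing_probability(con, prof, a[3]), 0.4 * prof$ac_boost)
})

test_that("probabilities are clamped to [0, 1]", {
  bb <- small_backbone(stem = 80L)
  prof <- plain_profile(baseline = 0.4, offset = -35L, fold = 4)
  a_pos <- reference_construct(bb)$a_pos_upper
  target <- a_pos[a_pos >= 36][1]
  con <- new_construct(bb,
    list(perturbation("mismatch", position = target + 34L, length = 3L)),
    id = "mm"
  )
  p <- editing_probability(con, prof, target)
  expect_equal(p, 1)
})

test_that("simulation is byte-identical for a fixed seed", {
  bb <- small_backbone(stem = 30L)
  lib <- assign_barcodes(generate_series(bb, "mismatch", size = 3)[1:5])
  cfg <- simulation_config(coverage_per_barcode = 50, rng_seed = 1, read_length = 40)
  s1 <- simulate_library_reads(lib, plain_profile(), cfg, withr::local_tempdir())
  s2 <- simulate_library_reads(lib, plain_profile(), cfg, withr::local_tempdir())
  expect_identical(readLines(s1$r1), readLines(s2$r1))
  expect_identical(readLines(s1$r2), readLines(s2$r2))
  s3 <- simulate_library_reads(
    lib, plain_profile(),
    simulation_config(coverage_per_barcode = 50, rng_seed = 2, read_length = 40),
    withr::local_tempdir()
  )
  expect_false(identical(readLines(s1$r1), readLines(s3$r1)))
})

test_that("a silent enzyme yields editing at or below the sequencing error rate", {
  bb <- small_backbone(stem = 40L)
  lib <- assign_barcodes(list(reference_construct(bb)))
  prof <- plain_profile(baseline = 0, fold = 1, suppression = flat_suppression())
  sim <- simulate_library_reads(
    lib, prof,
    simulation_config(coverage_per_barcode = 2000, rng_seed = 3, read_length = 50),
    withr::local_tempdir()
  )
  merged <- merge_and_filter_reads(sim$r1, sim$r2, lib)
  prof_out <- quantify_editing(merged, lib)[["perfect"]]
  expect_true(all(prof_out$percent <= 0.1 + 1e-9, na.rm = TRUE))
})

test_that("about half of the 44 adenosines are edited per molecule at baseline 0.5", {
  bb <- example_backbone() # 146-bp stem, 44 adenosines
  lib <- assign_barcodes(list(reference_construct(bb)))
  sim <- simulate_library_reads(
    lib, adar_profile("null"), # baseline 0.5, flat rules
    simulation_config(coverage_per_barcode = 1500, rng_seed = 4),
    withr::local_tempdir()
  )
  merged <- merge_and_filter_reads(sim$r1, sim$r2, lib)
  pmd <- per_molecule_distribution(merged, lib)
  ## binomial median at n = 44, p = 0.5
  expect_equal(qbinom(0.5, 44, 0.5), 22)
  expect_equal(pmd$summary$median, 22, tolerance = 0.05)
})

test_that("empirical per-position editing matches the generative probability", {
  bb <- small_backbone(stem = 50L)
  lib <- assign_barcodes(list(reference_construct(bb)))
  prof <- plain_profile(baseline = 0.3)
  sim <- simulate_library_reads(
    lib, prof,
    simulation_config(coverage_per_barcode = 4000, rng_seed = 5, read_length = 60),
    withr::local_tempdir()
  )
  merged <- merge_and_filter_reads(sim$r1, sim$r2, lib)
  ep <- quantify_editing(merged, lib)[["perfect"]]
  n <- attr(ep, "reads_used")
  ## each estimate inside the exact binomial 99% envelope of p = 0.30
  lo <- 100 * qbinom(0.005, n, 0.30) / n
  hi <- 100 * qbinom(0.995, n, 0.30) / n
  misses <- sum(ep$percent < lo - 0.15 | ep$percent > hi + 0.15)
  expect_lte(misses, 2) # ~1% expected failures over ~15 positions
})

test_that("symmetric profiles induce at the same per-strand upstream distance on both arms", {
  bb <- small_backbone(stem = 80L)
  prof <- plain_profile(baseline = 0.3, symmetric = TRUE)
  con <- new_construct(bb,
    list(perturbation("mismatch", position = 40L, length = 3L)),
    id = "mm"
  )
  peak_of <- function(arm) {
    a <- arm_pos <- if (arm == "upper") con$a_pos_upper else con$a_pos_lower
    p <- editing_probability(con, prof, a, arm = arm)
    center <- if (arm == "upper") 41L else 80L - 2L - 40L
    (a - center)[which.max(p)]
  }
  expect_equal(peak_of("upper"), peak_of("lower"), tolerance = 1)
  ## both peaks upstream (negative distance) on their own strand
  expect_lt(peak_of("lower"), 0)
})

test_that("a non-symmetric profile leaves the lower arm unedited", {
  bb <- small_backbone(stem = 30L)
  con <- reference_construct(bb)
  p <- editing_probability(con, plain_profile(symmetric = FALSE),
    con$a_pos_lower,
    arm = "lower"
  )
  expect_true(all(p == 0))
})

test_that("ground truth round-trips and is validated on read", {
  bb <- small_backbone(stem = 30L)
  lib <- assign_barcodes(list(reference_construct(bb)))
  sim <- simulate_library_reads(
    lib, plain_profile(),
    simulation_config(coverage_per_barcode = 20, rng_seed = 6, read_length = 40),
    withr::local_tempdir()
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$ground_truth, path, true_offset = -26L)
  back <- read_ground_truth(path, manifest_ids = "perfect")
  expect_equal(back$true_prob, sim$ground_truth$true_prob)
  expect_true(all(back$true_offset == -26L))

  ## corrupt probability
  gt_bad <- sim$ground_truth
  gt_bad$true_prob[1] <- 1.7
  write_ground_truth(gt_bad, path)
  expect_error(read_ground_truth(path), "outside")

  write_ground_truth(sim$ground_truth, path)
  expect_error(read_ground_truth(path, manifest_ids = "other"), "absent")
})

test_that("structured-element generator couples editing to downstream openness", {
  se <- simulate_structured_elements(100, adar_profile("adar1"), seed = 8)
  expect_equal(se$true_offset, 35)
  ## every elevated site is open at +35 by construction
  s <- se$sites
  open_at <- vapply(seq_len(nrow(s)), function(i) {
    rec <- se$structures[[s$structure_id[i]]]
    p <- s$position[i] + 35L
    p >= 0 && p < nchar(rec$sequence) && rec$element_labels[p + 1L] != "stem"
  }, logical(1))
  expect_identical(open_at, s$true_elevated)
  expect_gt(
    mean(s$editing_level[s$true_elevated]),
    mean(s$editing_level[!s$true_elevated]) + 10
  )

  ## null generator: no coupling anywhere
  sn <- simulate_structured_elements(50, adar_profile("null"), seed = 8)
  expect_true(is.na(sn$true_offset))
  expect_false(any(sn$sites$true_elevated))
  expect_error(simulate_structured_elements(0, adar_profile("adar1")), ">= 1")
})
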