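test_that("contact cutoff is inclusive at 4.5 A", {
  fib <- fake_fibril(data.frame(resno = 1, layer = 0, x = 0, y = 0, z = 0))
  mk <- function(d) fake_glycan(data.frame(hcg_id = 1L, unit = 1L,
                                           group_type = "OS6X",
                                           x = d, y = 0, z = 0))
  p <- contact_params()
  expect_equal(nrow(detect_contacts(rigid_pose(), fib, mk(4.4), p)), 1L)
  expect_equal(nrow(detect_contacts(rigid_pose(), fib, mk(4.5), p)), 1L)
  expect_equal(nrow(detect_contacts(rigid_pose(), fib, mk(4.6), p)), 0L)
  # several oxygens of one group collapse to one contact
  multi <- fake_glycan(data.frame(hcg_id = 1L, unit = 1L,
                                  group_type = "OS6X",
                                  x = c(3, 3.5, 4), y = 0, z = 0))
  ct <- detect_contacts(rigid_pose(), fib, multi, p)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$distance, 3)   # closest oxygen of the group
})

test_that("contact detection matches the brute-force oracle on random poses", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(8)
  p <- contact_params()
  set.seed(17)
  n_nonempty <- 0
  for (i in 1:100) {
    pose <- random_pose_near(fib$center, radius = runif(1, 3, 15))
    a <- detect_contacts(pose, fib, gly, p)
    b <- oracle_contacts(pose, fib, gly, p$cutoff)
    expect_equal(a[, c("resno", "layer", "hcg_id")], b)
    if (nrow(a)) n_nonempty <- n_nonempty + 1
  }
  expect_gt(n_nonempty, 10)
})

test_that("contact sets grow monotonically with the cutoff", {
  fib <- two_ladder_fibril(6)
  gly <- build_glycan(8)
  set.seed(19)
  pose <- random_pose_near(fib$center, radius = 8)
  keys <- lapply(c(3, 4.5, 6, 9), function(cut) {
    ct <- detect_contacts(pose, fib, gly, contact_params(cut))
    paste(ct$resno, ct$layer, ct$hcg_id)
  })
  for (i in 1:3) expect_true(all(keys[[i]] %in% keys[[i + 1]]))
})

test_that("frame counts use residue-by-layer and unique-HCG granularity", {
  expect_equal(frame_counts(data.frame(resno = integer(),
                                       layer = integer(),
                                       hcg_id = integer())),
               c(residues = 0L, hcgs = 0L))
  # one HCG touching three rungs of a ladder
  fr <- data.frame(resno = 311L, layer = 0:2, hcg_id = 1L)
  expect_equal(frame_counts(fr), c(residues = 3L, hcgs = 1L))
  # two HCGs on the same rung
  fr2 <- data.frame(resno = 311L, layer = 0L, hcg_id = 1:2)
  expect_equal(frame_counts(fr2), c(residues = 1L, hcgs = 2L))
})

test_that("median bound counts use the lower-median convention", {
  mkframe <- function(n) if (n == 0)
    data.frame(resno = integer(), layer = integer(), hcg_id = integer())
  else data.frame(resno = 1L, layer = seq_len(n) - 1L, hcg_id = 1L)
  s1 <- contact_series(lapply(c(3, 5, 6, 6, 7), mkframe))
  expect_equal(median_bound(s1, "residues")$median, 6)
  s2 <- contact_series(lapply(c(2, 4), mkframe))
  expect_equal(median_bound(s2, "residues")$median, 2)   # lower median
  s0 <- contact_series(lapply(c(0, 0, 0), mkframe))
  expect_equal(median_bound(s0, "residues")$median, 0)
  expect_equal(sum(median_bound(s1, "residues")$distribution), 1)
  # site filter restricts the count
  fr <- data.frame(resno = c(1L, 2L), layer = 0L, hcg_id = c(1L, 2L))
  s3 <- contact_series(list(fr))
  expect_equal(median_bound(s3, "residues", sites = 1L)$median, 1)
  expect_equal(median_bound(s3, "hcgs")$median, 2)
})

test_that("frequency map pools layers and averages per-frame indicators", {
  fib <- fake_fibril(data.frame(resno = rep(c(1L, 2L), each = 2),
                                layer = rep(0:1, 2),
                                x = rep(c(0, 30), each = 2), y = 0,
                                z = rep(c(0, 4.8), 2)))
  gly <- build_glycan(4)
  # frame A: unit-1 OS6X in contact with residue 1 on two layers
  hcg <- gly$hcgs[gly$hcgs$unit == 1 & gly$hcgs$group_type == "OS6X", ]
  frA <- data.frame(resno = 1L, layer = 0:1, hcg_id = hcg$hcg_id,
                    unit = 1L, group_type = "OS6X",
                    distance = 3)
  frB <- frA[0, ]
  series <- contact_series(list(frA, frB))
  fm <- frequency_map(series, gly, fib)
  expect_true(all(fm >= 0 & fm <= 1))
  expect_equal(fm["1:OS6X", "1"], 0.5)     # one of two frames, pooled layers
  expect_equal(sum(fm), 0.5)               # every other cell zero
  # marginal property: each cell equals the mean per-frame indicator
  ind <- vapply(series$frames, function(fr)
    any(fr$unit == 1 & fr$group_type == "OS6X" & fr$resno == 1),
    logical(1))
  expect_equal(fm["1:OS6X", "1"], mean(ind))
  # sulfamido rows can be folded out for figure parity
  fm2 <- frequency_map(series, gly, fib, include_sulfamido = FALSE)
  expect_false(any(grepl("N_sulfamido", rownames(fm2))))
  expect_true(any(grepl("N_sulfamido", rownames(fm))))
})

test_that("frequency maps render without error", {
  fib <- fake_fibril(data.frame(resno = 1L, layer = 0L, x = 0, y = 0,
                                z = 0))
  gly <- build_glycan(4)
  fm <- frequency_map(contact_series(list(
    detect_contacts(rigid_pose(t = c(2, 0, 0)), fib, gly))), gly, fib)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(fm))
  grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("contact series TSV round-trips through write", {
  fr <- data.frame(resno = 1L, layer = 0L, hcg_id = 2L, unit = 1L,
                   group_type = "OS6X", distance = 3.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_series(contact_series(list(fr, fr[0, ])), path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 1L)
  expect_equal(back$frame, 1L)
  expect_equal(back$resno, 1L)
})
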