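test_that("label_track validates intervals and round-trips through TSV", {
  tr <- label_track(c(0, 2, 5), c(1.5, 4, 6), c("inhalation",
                    "exhalation_acoustic", "nonbreathing"), duration_s = 8)
  expect_s3_class(tr, "label_track")
  expect_equal(attr(tr, "duration_s"), 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_track(tr, path)
  back <- read_label_track(path, duration_s = 8)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  expect_error(label_track(0, 0, "inhalation"), "start < end")
  expect_error(label_track(c(0, 1), c(2, 3),
                           c("inhalation", "inhalation")), "overlap")
  expect_error(label_track(0, 1, "breathy"), "unknown label")
})

test_that("rater merge averages close boundaries and flags >200 ms gaps", {
  a <- label_track(c(0.0, 3.0), c(1.00, 4.0),
                   c("exhalation_acoustic", "inhalation"), 6)
  b <- label_track(c(0.0, 3.0), c(1.10, 4.0),
                   c("exhalation_acoustic", "inhalation"), 6)
  m <- merge_raters(a, b)
  expect_equal(m$merged$end_s[1], 1.05)
  expect_equal(nrow(m$flags), 0)
  expect_equal(m$merged$label, c("exhalation_acoustic", "inhalation"))

  # 300 ms end difference: flagged, not auto-merged
  b2 <- label_track(c(0.0, 3.0), c(1.30, 4.0),
                    c("exhalation_acoustic", "inhalation"), 6)
  m2 <- merge_raters(a, b2)
  expect_equal(nrow(m2$flags), 1)
  expect_equal(m2$flags$rater_b_end, 1.3)
  expect_false(any(m2$merged$start_s == 0)) # flagged pair excluded

  # class conflict over the same span becomes unclear
  c1 <- label_track(1, 2, "inhalation", 6)
  c2 <- label_track(1, 2, "exhalation_acoustic", 6)
  m3 <- merge_raters(c1, c2)
  expect_equal(m3$merged$label, "unclear")
  expect_equal(nrow(m3$conflicts), 1)
})

test_that("rater merge is symmetric up to flag column order", {
  a <- label_track(c(0, 2.5, 5), c(1, 3.6, 6),
                   c("exhalation_airflow", "inhalation", "nonbreathing"), 8)
  b <- label_track(c(0.05, 2.4, 5.1), c(1.08, 3.5, 6.05),
                   c("exhalation_airflow", "inhalation", "nonbreathing"), 8)
  m_ab <- merge_raters(a, b)
  m_ba <- merge_raters(b, a)
  expect_equal(as.data.frame(m_ab$merged), as.data.frame(m_ba$merged))
})

test_that("frame grid projection: majority label, subtype collapse, unclear mask", {
  # grid-aligned track reproduces interval labels with no masking
  tr <- label_track(c(0, 0.195, 0.39), c(0.195, 0.39, 0.585),
                    c("exhalation_acoustic", "inhalation", "nonbreathing"), 1)
  fl <- frame_labels(tr, 3)
  expect_equal(fl$labels, c("exhalation", "inhalation", "nonbreathing"))
  expect_true(all(fl$mask))

  # 60% exhalation / 40% gap -> exhalation by majority
  tr2 <- label_track(0, 0.117, "exhalation_airflow", 0.195)
  expect_equal(frame_labels(tr2, 1)$labels, "exhalation")
  # minority overlap loses to the implicit nonbreathing gap
  tr3 <- label_track(0, 0.05, "exhalation_airflow", 0.195)
  expect_equal(frame_labels(tr3, 1)$labels, "nonbreathing")

  # any overlap with unclear masks the frame
  tr4 <- label_track(c(0, 0.194), c(0.194, 0.30),
                     c("inhalation", "unclear"), 1)
  fl4 <- frame_labels(tr4, 2)
  expect_false(fl4$mask[1])
  expect_false(fl4$mask[2])

  # exact 50/50 tie breaks by exhalation > inhalation priority
  tr5 <- label_track(c(0, 0.0975), c(0.0975, 0.195),
                     c("inhalation", "exhalation_acoustic"), 0.195)
  expect_equal(frame_labels(tr5, 1)$labels, "exhalation")
})

test_that("Cohen kappa: identity, hand-computed toy, chance level, relabeling", {
  x <- rep(phases, times = c(5, 3, 4))
  expect_equal(cohen_kappa(x, x)$kappa, 1)

  # 2-class toy: p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  a <- rep(c("exhalation", "nonbreathing", "exhalation", "nonbreathing"),
           times = c(40, 40, 10, 10))
  b <- rep(c("exhalation", "nonbreathing", "nonbreathing", "exhalation"),
           times = c(40, 40, 10, 10))
  k <- cohen_kappa(a, b)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.6)

  # independent uniform sequences: kappa near 0
  a10 <- seeded(24, sample(phases, 10000, replace = TRUE))
  b10 <- seeded(25, sample(phases, 10000, replace = TRUE))
  expect_lt(abs(cohen_kappa(a10, b10)$kappa), 0.05)

  # invariant under a consistent permutation of class names
  perm <- setNames(c("inhalation", "nonbreathing", "exhalation"), phases)
  expect_equal(cohen_kappa(perm[a10], perm[b10])$kappa,
               cohen_kappa(a10, b10)$kappa)

  # masked frames are dropped pairwise; empty overlap errors
  expect_equal(cohen_kappa(c(x, NA), c(x, "inhalation"))$kappa, 1)
  expect_error(cohen_kappa(NA_character_, "inhalation"), "unmasked")
})
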