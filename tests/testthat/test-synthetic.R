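test_that("session generation is seed-deterministic and invariant-respecting", {
  p <- synth_params(seed = 1)
  s1 <- generate_session(p, 1, seed = 77)
  s2 <- generate_session(p, 1, seed = 77)
  expect_identical(s1$acc, s2$acc)
  expect_identical(s1$timestamps, s2$timestamps)
  s3 <- generate_session(p, 1, seed = 78)
  expect_false(identical(s1$acc, s3$acc))
  # AccelSession invariants
  expect_true(all(diff(s1$timestamps) > 0))
  expect_true(all(is.finite(s1$acc)))
  expect_gte(session_duration(s1), p$duration[1] - 1 / p$sample_rate)
  expect_lte(session_duration(s1), p$duration[2])
})

test_that("severity zero collapses the two classes sample-for-sample", {
  p <- synth_params(dysk_severity = 0, seed = 2)
  s0 <- generate_session(p, 0, seed = 55)
  s1 <- generate_session(p, 1, seed = 55)
  expect_identical(s0$acc, s1$acc)
  expect_equal(s1$sim$severity, 0)
})

test_that("noiseless negative sessions concentrate PC1 power at the task frequency", {
  p <- synth_params(noise_sd = 0, seed = 3)
  for (i in 1:8) {
    s <- generate_session(p, 0, seed = 300 + i)
    sig <- project_pc1(global_rotation_align(s))
    v <- sig$values
    n <- length(v)
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))  # Hann window
    pw <- Mod(stats::fft(v * w))[2:(n %/% 2)]^2
    freqs <- (1:(n %/% 2 - 1)) * s$sample_rate / n
    k <- which.min(abs(freqs - s$sim$freq))
    frac <- sum(pw[max(1, k - 1):min(length(pw), k + 1)]) / sum(pw)
    expect_gte(frac, 0.95)
  }
})

test_that("cohort labels follow the prevalence within the binomial band", {
  p <- synth_params(n_subjects = 25, sessions_per_subject = c(2, 6),
                    prevalence = 0.3, seed = 13)
  coh <- generate_cohort(p)
  n <- nrow(coh$manifest)
  frac <- mean(coh$manifest$label)
  half_width <- 1.96 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), half_width + 1e-12)
  # per-subject effects shared across a subject's sessions
  s1 <- coh$sessions[["S001_01"]]
  s2 <- coh$sessions[["S001_02"]]
  expect_equal(s1$sim$freq, s2$sim$freq)
  expect_equal(s1$sim$amplitude, s2$sim$amplitude)
  # every generated session satisfies the container invariants
  for (s in coh$sessions) {
    expect_true(all(diff(s$timestamps) > 0))
    expect_true(all(is.finite(s$acc)))
    expect_true(s$label %in% c(0L, 1L))
  }
})

test_that("distinct cohort seeds give distinct sessions under one schema", {
  p1 <- synth_params(n_subjects = 4, sessions_per_subject = c(2, 2), seed = 5)
  p2 <- synth_params(n_subjects = 4, sessions_per_subject = c(2, 2), seed = 6)
  c1 <- generate_cohort(p1); c2 <- generate_cohort(p2)
  expect_identical(names(c1$manifest), names(c2$manifest))
  expect_false(identical(c1$sessions[[1]]$acc, c2$sessions[[1]]$acc))
})

test_that("cohorts round-trip through disk at the declared precision", {
  p <- synth_params(n_subjects = 3, sessions_per_subject = c(2, 2),
                    duration = c(6, 8), seed = 7)
  coh <- generate_cohort(p)
  dir <- withr::local_tempdir()
  write_cohort(coh$manifest, coh$sessions, dir)
  expect_error(write_cohort(coh$manifest, coh$sessions, dir), "force")
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(m$session_id, coh$manifest$session_id)
  expect_equal(m$label, coh$manifest$label)
  back <- read_cohort(m)
  for (id in names(back)) {
    expect_equal(back[[id]]$acc, coh$sessions[[id]]$acc, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(back[[id]]$timestamps, coh$sessions[[id]]$timestamps,
                 tolerance = 1e-9)
  }
  # empty cohort: manifest with header only
  dir2 <- withr::local_tempdir()
  write_cohort(coh$manifest[0, ], list(), dir2)
  expect_equal(nrow(utils::read.delim(file.path(dir2, "manifest.tsv"))), 0L)
})

test_that("the shifted-site preset changes noise, rate and gravity but keeps the schema", {
  base <- synth_params(n_subjects = 3, sessions_per_subject = c(2, 2), seed = 8)
  shift <- shifted_site_params(base)
  expect_equal(shift$noise_sd, 2 * base$noise_sd)
  expect_equal(shift$sample_rate, 30)
  expect_gt(acos(sum(shift$gravity_dir * base$gravity_dir)), 0.1)
  expect_equal(sqrt(sum(shift$gravity_dir^2)), 1, tolerance = 1e-12)
  coh <- generate_cohort(shift)
  expect_identical(names(coh$manifest),
                   c("file", "session_id", "subject_id", "dataset_tag",
                     "label", "task_tag"))
  expect_equal(coh$sessions[[1]]$sample_rate, 30, tolerance = 1e-6)
})

test_that("invalid parameters fail before generation", {
  expect_error(synth_params(prevalence = 0))
  expect_error(synth_params(prevalence = 1.2))
  expect_error(synth_params(sample_rate = -5))
  expect_error(synth_params(dysk_severity = 2))
  expect_error(generate_session(list(), 0, 1))
})
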