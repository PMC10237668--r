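make_token <- function(durations = c(100, 150)) {
  total <- sum(durations)
  segmented_token(
    data.frame(label = c("s", "@U"), duration = durations),
    contour(seq(0, total, length.out = 6),
            c(0, 0.5, 1, 0.5, -0.5, -1), label = "so"))
}

test_that("duration scaling preserves segment ratios exactly", {
  tok <- make_token(c(100, 150))
  scaled <- scale_duration(tok, 285)
  expect_equal(scaled$segments$duration, c(114, 171))  # factor 285/250
  expect_equal(token_duration(scaled), 285)
  expect_equal(duration(scaled$contour), 285)

  # identity when the target equals the current total
  same <- scale_duration(tok, 250)
  expect_equal(same$segments$duration, tok$segments$duration)
  expect_equal(same$contour$times, tok$contour$times)

  # ratio drift below 1e-9 over random tokens, including the 235 ms target
  set.seed(11)
  for (i in 1:20) {
    durs <- runif(sample(2:4, 1), 30, 200)
    ctr <- contour(c(0, cumsum(durs)), rnorm(length(durs) + 1))
    tok <- segmented_token(data.frame(label = paste0("ph", seq_along(durs)),
                                      duration = durs), ctr)
    scaled <- scale_duration(tok, 235)
    r0 <- tok$segments$duration / sum(tok$segments$duration)
    r1 <- scaled$segments$duration / sum(scaled$segments$duration)
    expect_lt(max(abs(r1 - r0) / r0), 1e-9)
    expect_equal(token_duration(scaled), 235)
  }
  expect_error(scale_duration(tok, 0), class = "argument_error")
})

test_that("gap removal shifts the connective and shortens the stimulus by the gap", {
  rec <- stimulus_record("clip_01", 1,
                         event_clause_contour = contour(c(0, 800), c(2, -2)),
                         connective = make_token(), gap_ms = 80)
  before <- stimulus_duration(rec)
  out <- remove_gap(rec)
  expect_equal(out$gap_ms, 0)
  expect_equal(out$connective_onset_ms, rec$connective_onset_ms - 80)
  expect_equal(stimulus_duration(out), before - 80)
  expect_equal(out$connective$contour$values, rec$connective$contour$values)
  # idempotent on a gapless record
  expect_equal(remove_gap(out)$connective_onset_ms, out$connective_onset_ms)
})

build_fixture <- function(n_pairs = 15, seed = 21) {
  params <- contour_gen_params()
  contours <- gen_contours(n_pairs, params, seed = seed)
  nc <- lapply(contours, normalize_time, grid_size = 101)
  fp <- fit_fpca(nc, 3)
  labels <- vapply(contours, `[[`, "", "label")
  clips <- lapply(seq_len(n_pairs), function(i) {
    ctr <- contours[grep("^objective", labels)][[i]]
    seg <- data.frame(label = c("s", "@U"),
                      duration = c(0.4, 0.6) * duration(ctr))
    stimulus_record(sprintf("clip_%02d", i), i,
                    event_clause_contour = contour(c(0, 800), c(2, -2)),
                    connective = segmented_token(seg, ctr), gap_ms = 80)
  })
  list(model = fp$model, clips = clips)
}

test_that("the stimulus builder yields 30 records at the condition targets", {
  fx <- build_fixture()
  records <- build_stimulus_set(fx$clips, fx$model)
  expect_length(records, 30)
  conds <- vapply(records, `[[`, "", "condition")
  expect_equal(sum(conds == "subjective"), 15)
  expect_equal(sum(conds == "objective"), 15)
  durs <- vapply(records, function(r) token_duration(r$connective), 0)
  expect_equal(unname(durs[conds == "subjective"]), rep(285, 15),
               tolerance = 1e-9)
  expect_equal(unname(durs[conds == "objective"]), rep(235, 15),
               tolerance = 1e-9)
  for (r in records) {
    tgt <- if (r$condition == "subjective") c(0.335, -0.065)
           else c(-0.515, 0.025)
    expect_equal(c(r$scores$s2, r$scores$s3), tgt)
    expect_equal(r$gap_ms, 0)
    # 58 pitch points at 285 ms / 5 ms, 48 at 235 ms
    expect_equal(length(r$connective$contour$times),
                 if (r$condition == "subjective") 58 else 48)
  }
})

test_that("building leaves the event clause bit-identical and preserves s1", {
  fx <- build_fixture(n_pairs = 3, seed = 8)
  clip <- fx$clips[[2]]
  spec <- prosody_spec("subjective")
  rec <- build_stimulus(clip, fx$model, spec)
  expect_identical(rec$event_clause_contour, clip$event_clause_contour)
  s1_orig <- project(fx$model,
                     normalize_time(clip$connective$contour, 101))$s1
  expect_equal(rec$scores$s1, s1_orig)
  # deterministic: identical inputs give identical records
  expect_identical(rec, build_stimulus(clip, fx$model, spec))
})

test_that("praat export round-trips the contour and counts intervals", {
  fx <- build_fixture(n_pairs = 2, seed = 13)
  rec <- build_stimulus(fx$clips[[1]], fx$model, prosody_spec("subjective"))
  base <- withr::local_tempfile()
  paths <- export_praat(rec, base)
  pt <- read_pitchtier(paths["pitchtier"])
  expect_length(pt$times, 58)
  expect_equal(pt$values, rec$connective$contour$values)
  tg <- read_textgrid(paths["textgrid"])
  expect_named(tg, c("clause", "segments"))
  expect_equal(nrow(tg$clause), 2)
  expect_equal(nrow(tg$segments), nrow(rec$connective$segments))
  expect_equal(tg$segments$text, rec$connective$segments$label)
  # segment boundaries exported at 0.1 ms resolution
  expect_equal(diff(c(tg$segments$xmin[1], tg$segments$xmax)),
               rec$connective$segments$duration, tolerance = 0.1)
})

test_that("both PitchTier dialects round-trip exactly", {
  ctr <- contour(seq(0, 285, by = 5), sin(seq(0, 285, by = 5) / 40),
                 label = "so")
  for (fmt in c("full", "short")) {
    path <- withr::local_tempfile(fileext = ".PitchTier")
    write_pitchtier(ctr, path, format = fmt)
    back <- read_pitchtier(path)
    expect_equal(back$times, ctr$times)
    expect_equal(back$values, ctr$values)
  }
})

test_that("degenerate tokens and bad records are rejected", {
  expect_error(segmented_token(data.frame(label = "s", duration = -1),
                               contour(c(0, 10), c(0, 1))),
               class = "degenerate_token_error")
  expect_error(
    segmented_token(data.frame(label = "s", duration = 500),
                    contour(c(0, 10), c(0, 1))),
    class = "invalid_contour_error")
  expect_error(stimulus_record("c", 1,
                               event_clause_contour = contour(c(0, 1), c(0, 0)),
                               connective = make_token(), gap_ms = -2),
               class = "argument_error")
})
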