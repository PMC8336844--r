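test_that("kde sampler draws from the smoothed empirical distribution", {
  set.seed(1)
  s <- kde_sampler(1:100, support = c(0, 101))
  x <- sampler_draw(s, 1e4)
  expect_true(all(x >= 0 & x <= 101))
  expect_lt(abs(mean(x) - 50.5), 1.5)
  # KS distance between draws and the kernel mixture CDF
  bw <- s$bandwidth
  mix_cdf <- function(q) vapply(q, function(qq) mean(pnorm(qq, 1:100, bw)), 0)
  grid <- seq(0, 101, length.out = 400)
  ks <- max(abs(ecdf(x)(grid) - mix_cdf(grid)))
  expect_lt(ks, 0.05)
})

test_that("kde sampler respects its support and degenerates gracefully", {
  set.seed(2)
  s <- kde_sampler(rep(5, 10), support = c(4, 6))
  expect_true(all(abs(sampler_draw(s, 1000) - 5) < 1e-6))
  s2 <- kde_sampler(c(0.3, 0.5, 1, 2, 3), support = c(0.25, 30))
  expect_true(all(sampler_draw(s2, 1e5) >= 0.25))
  expect_error(kde_sampler(1:3, c(0, 10)), "at least 5")
  expect_error(kde_sampler(1:10, c(10, 0)), "increasing")
  expect_error(kde_sampler(1:10, c(2, 5)), "within")
})

test_that("init_colony sets up counts, fates and phases", {
  init <- quick_init(14L, 2L, seed = 3L)
  expect_length(init$cells, 16L)
  fates <- vapply(init$cells, `[[`, "", "fate")
  expect_equal(sum(fates == "pluripotent"), 14L)
  expect_equal(sum(fates == "differentiated"), 2L)

  single <- quick_init(1L, 0L, seed = 4L)
  expect_length(single$cells, 1L)
  expect_error(init_colony(0, 0), "at least one")

  # synchronised + constant duration: all first divisions on the same frame
  sync <- constant_cycle_init(8L, duration_h = 10, phase_mode = "synchronised")
  nf <- vapply(sync$cells, `[[`, 0L, "n_frames")
  expect_equal(length(unique(nf)), 1L)
  expect_equal(nf[1], 120L)
})

test_that("initialisation is deterministic in the seed", {
  a <- quick_init(seed = 5L)
  b <- quick_init(seed = 5L)
  expect_identical(vapply(a$cells, `[[`, 0, "start_oct4"),
                   vapply(b$cells, `[[`, 0, "start_oct4"))
  expect_identical(vapply(a$cells, `[[`, 0, "cycle_duration"),
                   vapply(b$cells, `[[`, 0, "cycle_duration"))
})

test_that("zero division events returns exactly the founders with full series", {
  init <- quick_init(3L, 1L, seed = 6L)
  traj <- run_colony(init, preset("fig3_multiplicative"), 0, seed = 6L)
  expect_length(traj$cells, 4L)
  expect_equal(traj$n_division_events, 0L)
  for (cell in traj$cells) {
    expect_equal(length(cell$oct4), cell$n_frames + 1L)
    expect_equal(diff(cell$t), rep(5 / 60, cell$n_frames), tolerance = 1e-12)
  }
})

test_that("cell count bookkeeping: leaves = founders + events, records = founders + 2*events", {
  init <- quick_init(14L, 2L, seed = 7L)
  traj <- run_colony(init, preset("fig4_noise_switch"), 100, seed = 7L)
  expect_equal(traj$n_division_events, 100L)
  expect_length(traj$cells, 16L + 200L)
  ids <- vapply(traj$cells, `[[`, 0L, "cell_id")
  parents <- vapply(traj$cells, function(c) {
    if (is.na(c$parent_id)) NA_integer_ else c$parent_id
  }, 0L)
  leaves <- ids[!ids %in% parents]
  expect_length(leaves, 16L + 100L)
  # every mother has exactly two daughters
  expect_true(all(table(parents[!is.na(parents)]) == 2L))
})

test_that("daughters inherit the mother's pre-division value exactly", {
  init <- quick_init(4L, 0L, seed = 8L)
  traj <- run_colony(init, preset("fig3_multiplicative"), 40, seed = 8L)
  ids <- vapply(traj$cells, `[[`, 0L, "cell_id")
  for (cell in traj$cells) {
    if (is.na(cell$parent_id)) next
    mother <- traj$cells[[which(ids == cell$parent_id)]]
    expect_identical(cell$oct4[1], mother$oct4[length(mother$oct4)])
    expect_identical(cell$t[1], mother$t[length(mother$t)])
  }
})

test_that("colony runs are reproducible from the root seed", {
  a <- run_colony(quick_init(seed = 9L), preset("fig4_noise_switch"), 50, seed = 9L)
  b <- run_colony(quick_init(seed = 9L), preset("fig4_noise_switch"), 50, seed = 9L)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the dynamics model never alters the cycle-time distribution", {
  # same seed, different dynamics (including schedule changes): identical
  # lineage timing, because cycle draws use dedicated per-cell streams
  a <- run_colony(quick_init(seed = 10L), preset("fig4_noise_switch"), 60, seed = 10L)
  b <- run_colony(quick_init(seed = 10L), preset("fig5_time_K"), 60, seed = 10L)
  expect_identical(vapply(a$cells, `[[`, 0, "cycle_duration"),
                   vapply(b$cells, `[[`, 0, "cycle_duration"))
  expect_identical(vapply(a$cells, `[[`, 0, "birth_time"),
                   vapply(b$cells, `[[`, 0, "birth_time"))
})

test_that("synchronised constant cycles divide on multiples of T; asynchronous do not", {
  model <- preset("fig3_multiplicative")
  sync <- run_colony(constant_cycle_init(4L, duration_h = 10,
                                         phase_mode = "synchronised",
                                         seed = 11L),
                     model, 12, seed = 11L)
  births <- vapply(sync$cells, `[[`, 0, "birth_time")
  expect_true(all(abs(births %% 10) < 1e-9))

  async <- run_colony(constant_cycle_init(4L, duration_h = 10,
                                          phase_mode = "asynchronous",
                                          seed = 11L),
                      model, 12, seed = 11L)
  first_divs <- vapply(async$cells[5:length(async$cells)], `[[`, 0, "birth_time")
  expect_true(any(first_divs > 1e-9 & first_divs < 10 - 1e-9))
})

test_that("truncation clips series, drops late births and preserves the grid", {
  init <- quick_init(4L, 0L, seed = 12L)
  traj <- run_colony(init, preset("fig3_multiplicative"), 30, seed = 12L)
  t_top <- max(unlist(lapply(traj$cells, function(c) max(c$t))))
  expect_identical(as.data.frame(truncate_to_window(traj, t_top + 5)),
                   as.data.frame(traj))
  zero <- truncate_to_window(traj, 0)
  expect_length(zero$cells, 4L)
  expect_true(all(vapply(zero$cells, function(c) length(c$t), 0L) == 1L))
  clipped <- truncate_to_window(traj, 12)
  expect_true(all(unlist(lapply(clipped$cells, `[[`, "t")) <= 12 + 1e-9))
})

test_that("a 68-hour window on the 5-minute grid holds exactly 817 frame times", {
  init <- constant_cycle_init(1L, duration_h = 23, phase_mode = "synchronised",
                              seed = 13L)
  traj <- run_colony(init, preset("fig3_multiplicative"), 3, seed = 13L)
  clipped <- truncate_to_window(traj, 68)
  frames <- sort(unique(round(unlist(lapply(clipped$cells, `[[`, "t")) * 12)))
  expect_length(frames, 817L)
})

test_that("trajectory CSV round-trips with lineage and continuity intact", {
  init <- quick_init(3L, 1L, seed = 14L)
  traj <- run_colony(init, preset("fig4_noise_switch"), 20, seed = 14L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_length(back$cells, length(traj$cells))
  orig <- as.data.frame(traj)
  got <- as.data.frame(back)
  got <- got[order(got$cell_id, got$t_hours), ]
  orig <- orig[order(orig$cell_id, orig$t_hours), ]
  expect_equal(got$oct4_afu, signif(orig$oct4_afu, 6))
  expect_identical(got$fate, orig$fate)
})

test_that("malformed trajectory files are rejected with a reason", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("cell_id,parent_id,fate,t_hours,oct4_afu", path)
  expect_error(read_trajectory(path), "empty")
  writeLines(c("cell_id,parent_id,fate,t_hours,oct4_afu",
               "1,,pluripotent,0,100", "1,,pluripotent,0.25,110"), path)
  expect_error(read_trajectory(path), "grid")
  writeLines(c("cell_id,parent_id,fate,t_hours,oct4_afu",
               "2,1,pluripotent,0,100"), path)
  expect_error(read_trajectory(path), "parent")
})
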