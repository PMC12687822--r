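# Two-band world: land only at cell-center latitudes 0 and 60, where the
# cosine-latitude weights are 1 and 0.5
two_band_world <- function() {
  g <- grid_spec(-15, 75, -180, 180, 30, 120)
  lat <- grid_lats(g)  # 0, 30, 60
  is_land <- matrix(FALSE, g$n_lat, g$n_lon)
  is_land[lat %in% c(0, 60), ] <- TRUE
  land_mask(g, is_land)
}

test_that("pseudo-absence cells follow cosine-latitude weighting", {
  mask <- two_band_world()
  set.seed(1)
  rec <- sample_pseudo_absences(1e5, mask, integer(0),
                                as.Date(c("2022-01-01", "2022-12-31")))
  expect_equal(nrow(rec), 1e5)
  band <- rec$lat
  expect_true(all(band %in% c(0, 60)))
  counts <- c(sum(band == 0), sum(band == 60))
  # cos(0) : cos(60) = 2 : 1
  chi <- chisq.test(counts, p = c(2, 1) / 3)
  expect_gt(chi$p.value, 0.01)
  # dates uniform over the window
  expect_true(all(rec$date >= as.Date("2022-01-01") &
                    rec$date <= as.Date("2022-12-31")))
})

test_that("pseudo-absences never land on presence cells", {
  mask <- two_band_world()
  presence_cells <- which(as.vector(mask$is_land))[1:2]
  set.seed(2)
  rec <- sample_pseudo_absences(5000, mask, presence_cells,
                                as.Date(c("2022-06-01", "2022-06-30")))
  expect_false(any(rec$cell %in% presence_cells))
  # a world whose only land cell holds a presence has no support
  g1 <- grid_spec(0, 30, 0, 30, 30, 30)
  m1 <- land_mask(g1, matrix(TRUE, 1, 1))
  expect_error(sample_pseudo_absences(10, m1, 1L,
                                      as.Date(c("2022-01-01", "2022-01-31"))),
               "every land cell holds a presence")
})

test_that("build_dataset applies the absence-ratio semantics", {
  w <- memo("small_world", function()
    generate_world(world_config(n_lat = 10, n_lon = 20, years = 1,
                                seed = 2, effort = 0.05)))
  obs <- w$observations
  obs <- obs[as.Date(obs$date) >= w$cube$dates[1] + 10, , drop = FALSE][1:20, ]
  ds <- build_dataset(obs, sampling_config(0.2, seed = 1), w$mask,
                      w$derived, seq_len = 10)
  # ratio 0.2 -> five pseudo-absences per presence
  expect_equal(sum(ds$labels == 1), 20)
  expect_equal(sum(ds$labels == 0), 100)
  expect_false(any(ds$meta$cell[ds$labels == 0] %in%
                     ds$meta$cell[ds$labels == 1]))
  expect_true(all(is.finite(ds$features)))
  # ratio 1 balances the classes
  ds1 <- build_dataset(obs, sampling_config(1, seed = 1), w$mask,
                       w$derived, seq_len = 10)
  expect_equal(sum(ds1$labels == 0), sum(ds1$labels == 1))
})

test_that("random split reserves 20% of presences plus matched absences", {
  labels <- rep(c(1L, 0L), c(100, 500))
  ds <- structure(list(features = matrix(rnorm(600 * 3), 600, 3),
                       labels = labels,
                       meta = data.frame(cell = seq_len(600),
                                         date = as.Date("2022-01-01") +
                                           seq_len(600) %% 50,
                                         provenance = "x"),
                       seq_len = 1L, vars = "tmean"),
                  class = "labeled_dataset")
  sp <- split_random(ds, seed = 3)
  expect_equal(sum(sp$test$labels == 1), 20)
  expect_equal(sum(sp$test$labels == 0), 20)
  expect_equal(length(sp$train$labels) + length(sp$test$labels), 600)
  # disjoint and exhaustive
  expect_length(intersect(sp$test_idx, setdiff(seq_len(600), sp$test_idx)), 0)
  # deterministic given the seed
  sp2 <- split_random(ds, seed = 3)
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("chronological split reserves the newest presences", {
  labels <- rep(c(1L, 0L), c(10, 50))
  dates <- c(as.Date("2022-01-01") + 0:9,
             as.Date("2022-01-01") + sample(0:9, 50, replace = TRUE))
  ds <- structure(list(features = matrix(0, 60, 2), labels = labels,
                       meta = data.frame(cell = 1:60, date = dates,
                                         provenance = "x"),
                       seq_len = 1L, vars = "tmean"),
                  class = "labeled_dataset")
  sp <- split_chronological(ds, seed = 1)
  test_pres_dates <- as.Date(sp$test$meta$date[sp$test$labels == 1])
  expect_equal(sort(format(test_pres_dates)),
               c("2022-01-09", "2022-01-10"))
  expect_equal(sum(sp$test$labels == 0), 2)
  # no training presence is dated after any test presence
  train_pres_dates <- as.Date(sp$train$meta$date[sp$train$labels == 1])
  expect_true(max(train_pres_dates) <= min(test_pres_dates))
})

test_that("folds partition with balanced sizes and stratified labels", {
  labels <- rep(c(1L, 0L), c(83, 417))
  fold <- make_folds(labels, k = 5, seed = 7)
  expect_equal(sort(unique(fold)), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_per_fold <- tapply(labels, fold, sum)
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  # deterministic
  expect_identical(fold, make_folds(labels, k = 5, seed = 7))
})
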