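# Pseudo-absence generation and train/test splitting.
#
# Background ("pseudo-absence") points follow the presence/pseudo-absence
# recipe: dates uniform over the presence window, land cells drawn with
# probability proportional to the cosine of the cell-center latitude
# (area-proportional on a lat/lon grid), and any cell holding a presence
# excluded outright. The absence ratio is the presence : pseudo-absence
# count ratio, so ratio 0.2 means five background points per presence.

#' Sampling configuration
#'
#' @param absence_ratio Presence : pseudo-absence count ratio in `(0, 1]`
#'   (default 0.2, i.e. 5 background points per presence; the studied sweep
#'   is 0.1-0.5).
#' @param seed Integer RNG seed.
#' @param max_rejection_attempts Upper bound on date redraws per record when
#'   enforcing the climate-history constraint.
#' @export
sampling_config <- function(absence_ratio = 0.2, seed = 1L,
                            max_rejection_attempts = 1000L) {
  if (absence_ratio <= 0 || absence_ratio > 1)
    stop("absence_ratio must be in (0, 1]")
  structure(list(absence_ratio = absence_ratio, seed = as.integer(seed),
                 max_rejection_attempts = as.integer(max_rejection_attempts)),
            class = "sampling_config")
}

#' Draw pseudo-absence records
#'
#' Cells are drawn (with replacement) from land cells that hold no presence
#' observation, weighted by `cos(latitude)` of the cell center; dates are
#' uniform over `window`, restricted to dates leaving `seq_len` days of
#' climate history when `dates`/`seq_len` are given. Duplicate (cell, date)
#' pairs are allowed, matching independent draws.
#'
#' @param n Number of records.
#' @param mask A [land_mask()].
#' @param presence_cells Integer cell ids holding presences (excluded).
#' @param window Length-2 `Date` vector `(min, max)` of the presence window.
#' @param dates Optional cube date index (with `seq_len`) for the history
#'   constraint.
#' @param seq_len Optional sequence length in days.
#' @return Data frame with `date`, `cell`, `lat`, `lon` (cell centers).
#' @export
sample_pseudo_absences <- function(n, mask, presence_cells, window,
                                   dates = NULL, seq_len = NULL) {
  grid <- mask$grid
  land_cells <- which(as.vector(mask$is_land))
  valid <- setdiff(land_cells, presence_cells)
  if (!length(valid))
    stop("no valid pseudo-absence support: every land cell holds a presence")
  window <- as.Date(window)
  lo <- window[1]; hi <- window[2]
  if (!is.null(dates) && !is.null(seq_len)) {
    dates <- as.Date(dates)
    lo <- max(lo, dates[1] + seq_len)
    hi <- min(hi, dates[length(dates)])
  }
  if (lo > hi) stop("empty pseudo-absence date window after history constraint")
  w <- cos(cell_center(grid, valid)[, "lat"] * pi / 180)
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("all candidate cells have zero cosine-latitude weight")
  cell <- valid[sample.int(length(valid), n, replace = TRUE, prob = w)]
  date <- lo + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L
  ctr <- cell_center(grid, cell)
  data.frame(date = date, cell = cell, lat = ctr[, "lat"], lon = ctr[, "lon"])
}

#' Build a labeled presence/pseudo-absence dataset with features
#'
#' Joins presences and freshly sampled pseudo-absences with flattened
#' climate-sequence features. Presences lacking `seq_len` days of history
#' are dropped (with a count in attribute `n_dropped`); the number of
#' pseudo-absences is `round(n_presence / absence_ratio)`.
#'
#' @param presences An `observation_table` (see [read_observations()]).
#' @param config A [sampling_config()].
#' @param mask A [land_mask()].
#' @param derived A `derived_cube` from [derive_all()].
#' @param seq_len Sequence length in days.
#' @param vars Variable subset (default all five).
#' @return A `labeled_dataset`: list with `features` (matrix), `labels`
#'   (0/1 integer vector), and `meta` (data frame with `cell`, `date`,
#'   `provenance`).
#' @export
build_dataset <- function(presences, config, mask, derived, seq_len,
                          vars = derived_variables()) {
  stopifnot(inherits(config, "sampling_config"))
  d <- as.Date(presences$date)
  ok <- d >= derived$dates[1] + seq_len & d <= derived$dates[length(derived$dates)]
  n_dropped <- sum(!ok)
  pres <- presences[ok, , drop = FALSE]
  if (nrow(pres) == 0) stop("no presences with computable features")
  set.seed(config$seed)
  n_abs <- round(nrow(pres) / config$absence_ratio)
  abs_rec <- sample_pseudo_absences(n_abs, mask, unique(pres$cell),
                                    range(as.Date(pres$date)),
                                    derived$dates, seq_len)
  stopifnot(!any(abs_rec$cell %in% pres$cell))  # hard invariant
  cells <- c(pres$cell, abs_rec$cell)
  dts <- c(as.Date(pres$date), abs_rec$date)
  feats <- assemble_features(derived, cells, dts, seq_len, vars)
  ds <- structure(list(
    features = feats,
    labels = c(rep(1L, nrow(pres)), rep(0L, nrow(abs_rec))),
    meta = data.frame(
      cell = cells, date = dts,
      provenance = rep(c("presence", "pseudo_absence"),
                       c(nrow(pres), nrow(abs_rec))),
      stringsAsFactors = FALSE),
    seq_len = as.integer(seq_len), vars = vars),
    class = "labeled_dataset")
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Subset a labeled dataset by row indices
#' @param ds A `labeled_dataset`.
#' @param idx Integer row indices to keep.
#' @return A `labeled_dataset` with the selected rows.
#' @export
subset_dataset <- function(ds, idx) {
  structure(list(features = ds$features[idx, , drop = FALSE],
                 labels = ds$labels[idx],
                 meta = ds$meta[idx, , drop = FALSE],
                 seq_len = ds$seq_len, vars = ds$vars),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d rows (%d presence / %d pseudo-absence), %d features\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              ncol(x$features)))
  invisible(x)
}

#' Random 80/20 train/test split
#'
#' The test set holds `test_fraction` of the presences, chosen uniformly at
#' random, plus an equal number of randomly chosen pseudo-absences; all
#' remaining rows train.
#'
#' @param ds A `labeled_dataset`.
#' @param test_fraction Fraction of presences reserved for testing.
#' @param seed Integer seed (split is reproducible).
#' @return List with `train` and `test` datasets and the selected `test_idx`.
#' @export
split_random <- function(ds, test_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  pres <- which(ds$labels == 1L); abs <- which(ds$labels == 0L)
  n_t <- round(length(pres) * test_fraction)
  t_pres <- sort(sample(pres, n_t))
  t_abs <- sort(sample(abs, n_t))
  test_idx <- c(t_pres, t_abs)
  list(train = subset_dataset(ds, setdiff(seq_along(ds$labels), test_idx)),
       test = subset_dataset(ds, test_idx), test_idx = test_idx)
}

#' Chronological 80/20 train/test split
#'
#' The most recent `test_fraction` of presences (by date; ties broken by
#' stable input order) form the test presences, paired with an equal number
#' of randomly chosen pseudo-absences.
#'
#' @inheritParams split_random
#' @export
split_chronological <- function(ds, test_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  pres <- which(ds$labels == 1L); abs <- which(ds$labels == 0L)
  ord <- pres[order(as.Date(ds$meta$date[pres]))]  # stable: ties keep input order
  n_t <- round(length(pres) * test_fraction)
  t_pres <- if (n_t > 0) utils::tail(ord, n_t) else integer(0)
  t_abs <- sort(sample(abs, n_t))
  test_idx <- c(sort(t_pres), t_abs)
  list(train = subset_dataset(ds, setdiff(seq_along(ds$labels), test_idx)),
       test = subset_dataset(ds, test_idx), test_idx = test_idx)
}

#' Label-stratified k-fold assignment
#'
#' Partitions rows into `k` folds with sizes differing by at most one and
#' per-fold class balance within one row of the global balance.
#'
#' @param labels 0/1 label vector (or a `labeled_dataset`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per row.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (inherits(labels, "labeled_dataset")) labels <- labels$labels
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L  # rotate start fold between classes so totals stay balanced
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}
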