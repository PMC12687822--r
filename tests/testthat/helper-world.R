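# Shared fixtures and independent oracles for the test suite.
# Expensive artifacts (the default synthetic world and its trained model)
# are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small deterministic derived cube for feature/indexing tests:
# value = cell + day / 100 + var_index / 1000
tiny_derived_cube <- function(n_lat = 3, n_lon = 4, n_days = 12,
                              start = as.Date("2022-01-01")) {
  grid <- grid_spec(0, n_lat * 0.25, 0, n_lon * 0.25)
  dates <- seq(start, by = "day", length.out = n_days)
  vars <- derived_variables()
  arrs <- lapply(seq_along(vars), function(v) {
    a <- array(0, c(n_lat, n_lon, n_days))
    for (t in seq_len(n_days))
      a[, , t] <- matrix(seq_len(n_lat * n_lon), n_lat, n_lon) + t / 100 + v / 1000
    a
  })
  names(arrs) <- vars
  climate_cube(grid, dates, arrs, class = "derived_cube")
}

# default synthetic world (the reference study conditions)
default_world <- function() {
  memo("world", function() generate_world(world_config(seed = 1)))
}

# dataset and model under the reference conditions: seq_len 60, absence
# ratio 0.2, random 80/20 split, default training configuration
default_fit <- function() {
  memo("fit", function() {
    w <- default_world()
    ds <- build_dataset(w$observations, sampling_config(0.2, seed = 1),
                        w$mask, w$derived, seq_len = 60)
    sp <- split_random(ds, seed = 1)
    model <- train_full(sp$train, model_config(seed = 1, seq_len = 60))
    list(world = w, dataset = ds, split = sp, model = model)
  })
}

# --- independent oracles -------------------------------------------------

# exhaustive nearest-center search over every grid cell
oracle_snap <- function(lat, lon, grid) {
  ctr <- cell_center(grid, seq_len(n_cells(grid)))
  d2 <- (ctr[, "lat"] - lat)^2 + (ctr[, "lon"] - lon)^2
  cand <- which(d2 <= min(d2) + 1e-12)
  rc <- cell_rowcol(grid, cand)
  cand[order(rc[, "row"], rc[, "col"])][1]
}

# strictly-below counting by enumeration
oracle_fnr <- function(score, ref_scores) {
  vapply(score, function(s) sum(ref_scores < s), numeric(1)) / length(ref_scores)
}

# exhaustive O(365^2) circular-window season diameter (with earliest-start
# tie-break), independent of the two-pointer production code
oracle_season_diameter <- function(x, mass = 0.95) {
  n <- length(x)
  total <- sum(x)
  if (total <= 0) return(NA_integer_)
  target <- mass * total - 1e-9 * total
  css <- c(0, cumsum(c(x, x)))
  for (d in 1:n) {               # every length, shortest first
    sums <- css[(1:n) + d] - css[1:n]   # every circular start at once
    s <- which(sums >= target)[1]
    if (!is.na(s)) return(structure(d, start = s))
  }
  NA_integer_
}

# naive per-day per-variable lookup for flattened sequences
oracle_sequence <- function(cube, cell, date, seq_len, vars = derived_variables()) {
  rc <- cell_rowcol(cube$grid, cell)
  out <- numeric(0)
  for (k in seq_len:1) {
    d <- as.Date(date) - k
    t <- which(cube$dates == d)
    for (v in vars) out <- c(out, cube$vars[[v]][rc[1, "row"], rc[1, "col"], t])
  }
  out
}
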