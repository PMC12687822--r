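# Evaluation: rank-based AUC, leave-one/two-out covariate ablation, and
# Jaccard comparison of binarized risk maps.

#' Rank-based ROC AUC
#'
#' Mann-Whitney form: the probability that a random positive outranks a
#' random negative, with ties contributing 1/2. Because the statistic is
#' rank-based it gives identical results on raw scores and on any strictly
#' monotone transform of them (e.g. FNR values on tie-free data).
#'
#' @param values Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes")
  r <- rank(values)  # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# all subsets of `vars` obtained by removing 0, 1, ..., max_out variables
ablation_subsets <- function(vars, max_out = 2L) {
  subs <- list(vars)
  for (k in seq_len(min(max_out, length(vars) - 1L))) {
    drop_sets <- utils::combn(vars, k, simplify = FALSE)
    subs <- c(subs, lapply(drop_sets, function(d) setdiff(vars, d)))
  }
  subs
}

subset_label <- function(vars, subset) {
  out <- setdiff(vars, subset)
  if (!length(out)) "full" else paste0("-", paste(sort(out), collapse = ",-"))
}

#' Restrict a dataset to a variable subset
#'
#' Selects the feature columns of the named derived variables, preserving
#' the day-major layout; used by the ablation harness.
#' @param ds A `labeled_dataset`.
#' @param subset Character vector of variable names to keep.
#' @return A `labeled_dataset` with reduced feature columns.
#' @export
select_variable_columns <- function(ds, subset) {
  keep <- match(subset, ds$vars)
  if (anyNA(keep)) stop("unknown variable in subset")
  V <- length(ds$vars); L <- ds$seq_len
  cols <- as.vector(vapply(seq_len(L),
                           function(d) (d - 1L) * V + sort(keep),
                           integer(length(keep))))
  out <- ds
  out$features <- ds$features[, cols, drop = FALSE]
  out$vars <- ds$vars[sort(keep)]
  out
}

#' Leave-one/two-out covariate ablation
#'
#' Trains one model per (variable subset, sequence length, split type):
#' the full variable set, every leave-one-out subset, and every
#' leave-two-out subset (for 5 base variables: 1 + 5 + 10 = 16 subsets).
#' One pseudo-absence pool and one split are reused per sequence length so
#' AUC differences reflect the covariates, not resampling noise. Rows are
#' ranked by each subset's best AUC across sequence lengths (ties broken
#' lexicographically by subset label).
#'
#' @param presences An `observation_table`.
#' @param mask A [land_mask()].
#' @param derived A `derived_cube`.
#' @param base_variables Variables to ablate over (default all five).
#' @param seq_lens Sequence lengths to test (paper grid: 30, 60, 90, 365).
#' @param splits Split types, subset of `c("random", "chronological")`.
#' @param config A [model_config()] (its `seq_len`/`variable_subset` are
#'   overridden per row).
#' @param sampling A [sampling_config()].
#' @param max_out Maximum number of variables removed (default 2).
#' @param cv_folds If > 0, also run k-fold CV per row and record per-fold
#'   AUCs (costly; default 0 records test AUC only).
#' @return An `ablation_result` data frame with columns `subset`,
#'   `seq_len`, `split`, `auc`, `rank`, and optionally `cv_auc_*`.
#' @export
ablation <- function(presences, mask, derived,
                     base_variables = derived_variables(),
                     seq_lens = c(30L, 60L, 90L, 365L),
                     splits = c("random", "chronological"),
                     config = model_config(), sampling = sampling_config(),
                     max_out = 2L, cv_folds = 0L) {
  if (length(base_variables) < 1) stop("need at least one base variable")
  subs <- ablation_subsets(base_variables, max_out)
  rows <- list()
  for (sl in seq_lens) {
    ds <- build_dataset(presences, sampling, mask, derived, sl,
                        vars = base_variables)
    for (sp in splits) {
      split <- if (sp == "random") split_random(ds, seed = sampling$seed)
               else split_chronological(ds, seed = sampling$seed)
      for (sub in subs) {
        cfg <- config
        cfg$seq_len <- as.integer(sl)
        cfg$variable_subset <- sub
        tr <- select_variable_columns(split$train, sub)
        te <- select_variable_columns(split$test, sub)
        fit <- train_full(tr, cfg)
        auc <- roc_auc(predict_scores(fit, te$features), te$labels)
        row <- data.frame(subset = subset_label(base_variables, sub),
                          n_vars = length(sub), seq_len = sl, split = sp,
                          auc = auc, stringsAsFactors = FALSE)
        if (cv_folds > 0) {
          cv <- cross_validate(tr, cfg, k = cv_folds)
          row$cv_mean_auc <- cv$mean_auc
          row$cv_sd_auc <- cv$sd_auc
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  best <- tapply(out$auc, out$subset, max)
  ord <- order(-best[out$subset], out$subset)
  out <- out[ord, , drop = FALSE]
  out$rank <- match(out$subset, unique(out$subset))
  rownames(out) <- NULL
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Jaccard similarity of two binarized risk maps
#'
#' Binarizes each map at `FNR >= threshold` and returns intersection over
#' union of the exceedance sets. Cells missing in either map are excluded.
#' Two empty exceedance sets compare as identical (similarity 1).
#'
#' @param map_a,map_b FNR matrices on the same grid.
#' @param threshold FNR threshold in `[0, 1]`.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_maps <- function(map_a, map_b, threshold) {
  stopifnot(all(dim(map_a) == dim(map_b)), threshold >= 0, threshold <= 1)
  ok <- !is.na(map_a) & !is.na(map_b)
  a <- map_a[ok] >= threshold
  b <- map_b[ok] >= threshold
  uni <- sum(a | b)
  if (uni == 0) return(1.0)
  sum(a & b) / uni
}

#' Jaccard comparison matrix over threshold pairs
#'
#' Entry `[i, j]` is the Jaccard similarity of map A binarized at
#' `thresholds[i]` versus map B at `thresholds[j]`, reproducing the
#' binary-comparison-matrix view of two risk maps.
#'
#' @inheritParams jaccard_maps
#' @param thresholds Numeric vector of FNR thresholds.
#' @return `|thresholds| x |thresholds|` matrix.
#' @export
jaccard_matrix <- function(map_a, map_b, thresholds) {
  stopifnot(all(dim(map_a) == dim(map_b)))
  n <- length(thresholds)
  out <- matrix(NA_real_, n, n,
                dimnames = list(format(thresholds), format(thresholds)))
  ok <- !is.na(map_a) & !is.na(map_b)
  va <- map_a[ok]; vb <- map_b[ok]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- va >= thresholds[i]; b <- vb >= thresholds[j]
    uni <- sum(a | b)
    out[i, j] <- if (uni == 0) 1.0 else sum(a & b) / uni
  }
  out
}
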