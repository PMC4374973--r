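#' Build a balanced Stroop block
#'
#' Crosses the task dimension (strong "word reading" vs weak "colour
#' naming") with condition (congruent, incongruent, neutral), with
#' `n_per_cell` trials per cell.  Congruent trials co-activate the same
#' feature level on both dimensions, incongruent trials different levels,
#' and neutral trials present only the task-relevant dimension's feature.
#'
#' @param n_per_cell trials per task x condition cell.
#' @param seed integer seed for the feature draws.
#' @param n_features feature levels per dimension.
#' @return a data frame of class `xt_stroop_block` with columns
#'   `task_dimension`, `condition`, `strong_feature`, `weak_feature`.
#' @export
build_stroop_block <- function(n_per_cell = 16, seed = 1, n_features = 4) {
  stopifnot(n_per_cell >= 1)
  cells <- expand.grid(task_dimension = c("strong", "weak"),
                       condition = c("congruent", "incongruent", "neutral"),
                       rep = seq_len(n_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells)
  with_seed(seed, {
    rel <- sample.int(n_features, n, replace = TRUE)
    other <- ((rel - 1L + sample.int(n_features - 1L, n, replace = TRUE)) %%
                n_features) + 1L
    strong <- ifelse(cells$task_dimension == "strong", rel,
                     ifelse(cells$condition == "congruent", rel,
                            ifelse(cells$condition == "incongruent", other,
                                   NA)))
    weak <- ifelse(cells$task_dimension == "weak", rel,
                   ifelse(cells$condition == "congruent", rel,
                          ifelse(cells$condition == "incongruent", other,
                                 NA)))
    block <- data.frame(task_dimension = cells$task_dimension,
                        condition = cells$condition,
                        strong_feature = as.integer(strong),
                        weak_feature = as.integer(weak))
    class(block) <- c("xt_stroop_block", "data.frame")
    block
  })
}

#' Run a Stroop block
#'
#' Pure performance test: each trial clamps the stimulus (co-activated
#' strong- and weak-dimension features) together with the dimension cue
#' for the task-relevant dimension, settles with learning and gating
#' plasticity off, and records the settling time of the response label
#' (the feature-column activity that constitutes the vocal output) in
#' cycles as the reaction-time analog; full-network settling times are
#' kept in `settle_cycles`.  Non-converged trials are flagged and
#' excluded from cell means.
#'
#' @param net a trained `xt_network`.
#' @param block an [build_stroop_block()] data frame.
#' @return an object of class `xt_stroop`: the per-trial data frame
#'   (`cycles`, `converged`, `response`, `correct` added) and a `cells`
#'   summary of mean settling cycles per task x condition.
#' @export
run_stroop <- function(net, block) {
  stopifnot(inherits(net, "xt_network"))
  cfg <- net$config
  n <- nrow(block)
  nf <- cfg$n_features
  sd_ <- cfg$strong_dimension
  wd <- cfg$weak_dimension
  in1 <- matrix(0, n, cfg$n_input)
  has_s <- !is.na(block$strong_feature)
  has_w <- !is.na(block$weak_feature)
  in1[cbind(which(has_s), feature_id(sd_, block$strong_feature[has_s], nf))] <- 1
  in1[cbind(which(has_w), feature_id(wd, block$weak_feature[has_w], nf))] <- 1
  rel_dim <- ifelse(block$task_dimension == "strong", sd_, wd)
  rel_feat <- ifelse(block$task_dimension == "strong",
                     block$strong_feature, block$weak_feature)
  target <- feature_id(rel_dim, rel_feat, nf)
  res <- cpp_run_trials(net$weights, cfg, in1, matrix(0, n, cfg$n_input),
                        rep(3L, n), as.integer(rel_dim) - 1L,
                        as.integer(target) - 1L,
                        numeric(cfg$n_pfc), numeric(cfg$n_pfc + 1),
                        numeric(cfg$n_pfc),
                        1, 0, 0, 0, 0, 1, cfg$delta_tol, 0,
                        matrix(0, 1, cfg$n_pfc), FALSE, FALSE)
  trials <- block
  trials$cycles <- as.integer(res$label_cycles)
  trials$settle_cycles <- as.integer(res$cycles)
  trials$converged <- as.logical(res$converged)
  trials$response <- ifelse(res$response < 0, NA_integer_,
                            res$response + 1L)
  trials$correct <- as.logical(res$correct)
  ok <- trials$converged
  cells <- aggregate(cycles ~ task_dimension + condition,
                     data = trials[ok, , drop = FALSE], FUN = mean)
  names(cells)[names(cells) == "cycles"] <- "mean_cycles"
  counts <- aggregate(converged ~ task_dimension + condition, data = trials,
                      FUN = function(z) sum(!z))
  names(counts)[names(counts) == "converged"] <- "n_excluded"
  cells <- merge(cells, counts, by = c("task_dimension", "condition"))
  structure(list(trials = trials, cells = cells),
            class = "xt_stroop")
}

#' @export
print.xt_stroop <- function(x, ...) {
  cat("<xt_stroop>\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Fit the millisecond scaling of settling times
#'
#' A single multiplicative scale chosen so that the model's mean settling
#' time in the congruent strong-task (word reading) condition matches a
#' mean human reaction time; the scale is then applied unchanged to every
#' condition.
#'
#' @param model_mean_cycles_congruent_strong mean settling cycles in the
#'   congruent word-reading cell.
#' @param human_mean_ms mean human RT (ms) for the same condition.
#' @return scale in ms per cycle.
#' @export
fit_rt_scale <- function(model_mean_cycles_congruent_strong, human_mean_ms) {
  if (model_mean_cycles_congruent_strong <= 0 || human_mean_ms <= 0)
    stop("both means must be positive")
  human_mean_ms / model_mean_cycles_congruent_strong
}

#' Stroop interference
#'
#' Mean reaction time in the incongruent condition minus the congruent
#' condition for one task dimension, computed over converged trials.  With
#' the default `scale = 1` the result is in settling cycles; pass a scale
#' from [fit_rt_scale()] for milliseconds (conclusions are invariant to
#' the scale).
#'
#' @param result an `xt_stroop` result.
#' @param task_dimension `"weak"` (colour naming) or `"strong"` (word
#'   reading).
#' @param scale ms-per-cycle factor (default 1: cycles).
#' @return interference (incongruent minus congruent mean RT).
#' @export
stroop_interference <- function(result, task_dimension = "weak", scale = 1) {
  stopifnot(inherits(result, "xt_stroop"))
  tr <- result$trials
  pick <- function(cond) {
    z <- tr$cycles[tr$task_dimension == task_dimension &
                   tr$condition == cond & tr$converged]
    if (!length(z)) stop("empty ", cond, " cell for task ", task_dimension)
    mean(z)
  }
  scale * (pick("incongruent") - pick("congruent"))
}
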