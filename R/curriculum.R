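#' Developmental curriculum configuration
#'
#' Parameters of the developmental training regime: epochs of `epoch_size`
#' supervised trials over the factorial stimulus space, alternated with
#' generalization probes of `test_trials` novel-stimulus trials, stopping
#' at `criterion_error` or after `max_epochs`.  One dimension (the future
#' "colour naming" pathway) is experienced as relevant only
#' `weak_frequency_ratio` times as often as each other dimension.
#'
#' @param n_dimensions,n_features factorial stimulus space (5 x 4).
#' @param epoch_size trials per training epoch (default 2000).
#' @param max_epochs maximum training epochs (default 100).
#' @param criterion_error generalization error bound (default 0.10).
#' @param test_trials generalization sample size (default 250).
#' @param weak_dimension index of the under-trained dimension.
#' @param weak_frequency_ratio relevance frequency of the weak dimension
#'   relative to each other dimension (default 0.25).
#' @param novel_fraction fraction of the stimulus space reserved as novel
#'   items never used in training (default 0.2).
#' @return a list of class `xt_curriculum_config`.
#' @export
curriculum_config <- function(n_dimensions = 5, n_features = 4,
                              epoch_size = 2000, max_epochs = 100,
                              criterion_error = 0.10, test_trials = 250,
                              weak_dimension = 5,
                              weak_frequency_ratio = 0.25,
                              novel_fraction = 0.2) {
  if (criterion_error <= 0 || criterion_error >= 1)
    stop("criterion_error must lie in (0, 1)")
  if (weak_frequency_ratio <= 0 || weak_frequency_ratio > 1)
    stop("weak_frequency_ratio must lie in (0, 1]")
  structure(list(n_dimensions = as.integer(n_dimensions),
                 n_features = as.integer(n_features),
                 epoch_size = as.integer(epoch_size),
                 max_epochs = as.integer(max_epochs),
                 criterion_error = criterion_error,
                 test_trials = as.integer(test_trials),
                 weak_dimension = as.integer(weak_dimension),
                 weak_frequency_ratio = weak_frequency_ratio,
                 novel_fraction = novel_fraction),
            class = "xt_curriculum_config")
}

#' The factorial stimulus space
#'
#' All feature assignments over `n_dimensions` dimensions with `n_features`
#' levels each (4^5 = 1024 by default), one stimulus per row.  Row `i`
#' equals `1 + sum((f_d - 1) * n_features^(d - 1))`, so row indices double
#' as stimulus codes.
#'
#' @param n_dimensions,n_features stimulus space shape.
#' @return integer matrix, rows = stimuli, columns = dimensions, entries =
#'   feature levels (1-based).
#' @export
factorial_stimuli <- function(n_dimensions = 5, n_features = 4) {
  g <- do.call(expand.grid, rep(list(seq_len(n_features)), n_dimensions))
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, paste0("dim", seq_len(n_dimensions)))
  storage.mode(m) <- "integer"
  m
}

stimulus_code <- function(feats, n_features) {
  nd <- ncol(feats)
  as.integer((feats - 1L) %*% n_features^(seq_len(nd) - 1) + 1L)
}

#' Partition the stimulus space into training and novel pools
#'
#' A seeded random `novel_fraction` of the full factorial space is held out
#' as novel items that never appear in training trials; the partition is
#' deterministic given the seed, and every individual feature is guaranteed
#' to appear in the training pool.
#'
#' @param seed integer seed.
#' @param config an [curriculum_config()] list.
#' @return list with integer index vectors `train` and `novel` (disjoint,
#'   jointly covering all stimuli).
#' @export
split_stimuli <- function(seed = 1, config = curriculum_config()) {
  with_seed(seed, split_stimuli_impl(config))
}

split_stimuli_impl <- function(config) {
  stim <- factorial_stimuli(config$n_dimensions, config$n_features)
  n <- nrow(stim)
  n_novel <- round(config$novel_fraction * n)
  for (try in 1:100) {
    novel <- sort(sample.int(n, n_novel))
    train <- setdiff(seq_len(n), novel)
    counts <- apply(stim[train, , drop = FALSE], 2, tabulate,
                    nbins = config$n_features)
    if (all(counts > 0)) return(list(train = train, novel = novel))
  }
  stop("could not build a split with full feature coverage")
}

#' Sample developmental trials
#'
#' Draws `n` trials: the task uniformly over naming, matching, comparison
#' and cued naming; the relevant dimension with the weak dimension's
#' probability scaled by `weak_frequency_ratio`; and stimuli from the given
#' pool.  Matching trials pair stimuli that share their feature only on the
#' relevant dimension (the target is the shared feature); comparison trials
#' pair stimuli that differ on the cued dimension (the target is the higher
#' feature level); cued naming presents a sparse stimulus carrying only the
#' relevant and one distractor dimension (the Stroop trial format).  The
#' dimension cue is on for every developmental trial.
#'
#' Draws use the caller's R random stream; seed upstream for
#' reproducibility.
#'
#' @param n number of trials.
#' @param config an [curriculum_config()] list.
#' @param pool integer vector of stimulus row indices available for
#'   sampling (see [split_stimuli()]); default: the full space.
#' @return a list with `trials` (a data frame: task, dimension, stimulus
#'   codes, target id) and the clamped input arrays `in1`, `in2` plus
#'   integer vectors `task`, `cue`, `target` consumed by the engine.
#' @export
sample_trials <- function(n, config = curriculum_config(), pool = NULL) {
  nd <- config$n_dimensions; nf <- config$n_features
  stim <- factorial_stimuli(nd, nf)
  if (is.null(pool)) pool <- seq_len(nrow(stim))
  if (!length(pool)) stop("stimulus pool is empty")
  task <- sample.int(4L, n, replace = TRUE)
  w <- rep(1, nd); w[config$weak_dimension] <- config$weak_frequency_ratio
  dm <- sample.int(nd, n, replace = TRUE, prob = w / sum(w))
  s1 <- pool[sample.int(length(pool), n, replace = TRUE)]
  F1 <- stim[s1, , drop = FALSE]
  lev1 <- F1[cbind(seq_len(n), dm)]
  pool_member <- logical(nrow(stim)); pool_member[pool] <- TRUE
  s2 <- rep(NA_integer_, n)

  # matching: same level on the relevant dimension, different on all others
  mi <- which(task == 2L)
  un <- mi
  for (iter in 1:12) {
    if (!length(un)) break
    M2 <- F1[un, , drop = FALSE]
    offs <- matrix(sample.int(nf - 1L, length(un) * nd, replace = TRUE),
                   length(un), nd)
    offs[cbind(seq_along(un), dm[un])] <- 0L
    M2 <- ((M2 - 1L + offs) %% nf) + 1L
    c2 <- stimulus_code(M2, nf)
    ok <- pool_member[c2]
    s2[un[ok]] <- c2[ok]
    un <- un[!ok]
  }
  for (i in un) {  # rare fallback: exhaustive candidate search
    cand <- pool[stim[pool, dm[i]] == lev1[i] & pool != s1[i]]
    diffs <- rowSums(stim[cand, -dm[i], drop = FALSE] ==
                     matrix(F1[i, -dm[i]], length(cand), nd - 1,
                            byrow = TRUE)) == 0
    cand <- cand[diffs]
    if (!length(cand)) stop("no matching partner available in pool")
    s2[i] <- cand[sample.int(length(cand), 1)]
  }

  # comparison: partner differs on the cued dimension
  ci <- which(task == 3L)
  un <- ci
  for (iter in 1:24) {
    if (!length(un)) break
    cand <- pool[sample.int(length(pool), length(un), replace = TRUE)]
    ok <- stim[cand, , drop = FALSE][cbind(seq_along(un), dm[un])] != lev1[un]
    s2[un[ok]] <- cand[ok]
    un <- un[!ok]
  }
  if (length(un)) stop("no comparison partner available in pool")

  # cued naming: distractor dimension for the sparse stimulus
  od <- ((dm - 1L + sample.int(nd - 1L, n, replace = TRUE)) %% nd) + 1L

  target_lev <- lev1
  if (length(ci)) {
    lev2 <- stim[s2[ci], , drop = FALSE][cbind(seq_along(ci), dm[ci])]
    target_lev[ci] <- pmax(lev1[ci], lev2)
  }
  target <- feature_id(dm, target_lev, nf)

  in1 <- matrix(0, n, nd * nf)
  in2 <- matrix(0, n, nd * nf)
  full <- which(task != 4L)
  for (d in seq_len(nd))
    in1[cbind(full, feature_id(d, F1[full, d], nf))] <- 1
  q <- which(task == 4L)
  if (length(q)) {
    in1[cbind(q, feature_id(dm[q], lev1[q], nf))] <- 1
    in1[cbind(q, feature_id(od[q], F1[cbind(q, od[q])], nf))] <- 1
  }
  two <- which(task %in% c(2L, 3L))
  if (length(two)) {
    F2 <- stim[s2[two], , drop = FALSE]
    for (d in seq_len(nd))
      in2[cbind(two, feature_id(d, F2[, d], nf))] <- 1
  }
  trials <- data.frame(task = XT_TASKS[task], dimension = dm,
                       s1 = s1, s2 = s2, distractor = ifelse(task == 4L, od, NA),
                       target = target)
  list(trials = trials, in1 = in1, in2 = in2,
       task = task, cue = dm, target = target)
}

#' Generalization test on novel stimuli
#'
#' Runs `n_trials` trials drawn from the novel pool with learning and
#' gating plasticity off and maintenance currents cleared, and returns the
#' fraction answered incorrectly (no response counts as an error).
#'
#' @param net an `xt_network`.
#' @param pool integer vector of novel stimulus indices.
#' @param n_trials number of test trials (default 250).
#' @param config an [curriculum_config()] list.
#' @param seed optional seed; when `NULL`, the caller's random stream is
#'   used.
#' @return error rate in `[0, 1]`, with attributes `n_trials` and
#'   `correct` (the per-trial flags).
#' @export
evaluate_generalization <- function(net, pool, n_trials = 250,
                                    config = curriculum_config(),
                                    seed = NULL) {
  run <- function() {
    tr <- sample_trials(n_trials, config, pool)
    cfg <- net$config
    res <- cpp_run_trials(net$weights, cfg, tr$in1, tr$in2,
                          tr$task - 1L, tr$cue - 1L, tr$target - 1L,
                          numeric(cfg$n_pfc), numeric(cfg$n_pfc + 1),
                          numeric(cfg$n_pfc),
                          1, 0, 0, 0, 0, 1, cfg$delta_tol, 0,
                          matrix(0, 1, cfg$n_pfc), FALSE, FALSE)
    err <- 1 - mean(res$correct)
    attr(err, "n_trials") <- n_trials
    attr(err, "correct") <- as.logical(res$correct)
    err
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Develop a network to criterion
#'
#' The full developmental loop: builds a seeded network and critic, then
#' alternates epochs of `epoch_size` supervised trials — with the adaptive
#' gate and critic active throughout, and the TD error scaled by `kappa`
#' from the very beginning — with generalization tests on novel stimuli.
#' Training stops when the generalization error reaches the criterion (or
#' after `max_epochs`; with `stop_at_criterion = FALSE` it always runs the
#' full `max_epochs`, as in developmental-trajectory studies).  Failure to
#' reach criterion is reported as an outcome, not an error.
#'
#' @param kappa dopamine efficacy in `(0, 1]` applied to the TD error.
#' @param seed master seed; the run is fully reproducible given
#'   `(kappa, seed, config, net_config)`.
#' @param config an [curriculum_config()] list.
#' @param net_config an [xt_config()] list.
#' @param stop_at_criterion stop as soon as the criterion is met.
#' @param probe optional `function(net, critic, epoch)` evaluated on a
#'   frozen copy after each `probe_every`-th epoch; its results are
#'   collected in the `probes` element.
#' @param probe_every epoch interval between probes.
#' @return an object of class `xt_development`: the trained `network` and
#'   `critic`, a per-epoch `trace` data frame (epoch, train_error,
#'   generalization_error, criterion_met), `probes`, `criterion_met`,
#'   `epochs_run`, and the call parameters.
#' @export
run_development <- function(kappa = 1, seed = 1,
                            config = curriculum_config(),
                            net_config = xt_config(),
                            stop_at_criterion = TRUE,
                            probe = NULL, probe_every = 1) {
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  net <- build_xt_network(net_config, seed = derive_seed(seed, 1))
  critic <- new_critic(net_config$n_pfc, gamma = net_config$gamma,
                       kappa = kappa, alpha = net_config$alpha)
  out <- with_seed(derive_seed(seed, 2), {
    pools <- split_stimuli_impl(config)
    trace <- vector("list", config$max_epochs)
    probes <- list()
    criterion_met <- FALSE
    epochs_run <- 0
    cfg <- net$config
    for (epoch in seq_len(config$max_epochs)) {
      tr <- sample_trials(config$epoch_size, config, pools$train)
      noise <- matrix(rnorm(config$epoch_size * cfg$n_pfc),
                      config$epoch_size, cfg$n_pfc)
      res <- cpp_run_trials(net$weights, cfg, tr$in1, tr$in2,
                            tr$task - 1L, tr$cue - 1L, tr$target - 1L,
                            net$maintenance, c(critic$weights, critic$bias),
                            net$noise_pending,
                            kappa, cfg$alpha, cfg$maintenance_gain,
                            cfg$noise_sd, cfg$gate_floor, cfg$gate_power,
                            cfg$delta_tol, cfg$lrate,
                            noise, TRUE, TRUE)
      net$weights <- res$weights
      net$maintenance <- as.numeric(res$maintenance)
      net$noise_pending <- as.numeric(res$noise_pending)
      cw <- as.numeric(res$critic)
      critic$weights <- cw[seq_len(cfg$n_pfc)]
      critic$bias <- cw[cfg$n_pfc + 1]
      gen_err <- evaluate_generalization(net, pools$novel,
                                         config$test_trials, config)
      met <- gen_err <= config$criterion_error
      trace[[epoch]] <- data.frame(epoch = epoch,
                                   train_error = 1 - mean(res$correct),
                                   generalization_error = as.numeric(gen_err),
                                   criterion_met = met)
      epochs_run <- epoch
      if (!is.null(probe) && epoch %% probe_every == 0)
        probes[[as.character(epoch)]] <- probe(net, critic, epoch)
      if (met) criterion_met <- TRUE
      if (met && stop_at_criterion) break
    }
    list(trace = do.call(rbind, trace[seq_len(epochs_run)]),
         probes = probes, criterion_met = criterion_met,
         epochs_run = epochs_run, pools = pools)
  })
  structure(list(network = net, critic = critic, trace = out$trace,
                 probes = out$probes, criterion_met = out$criterion_met,
                 epochs_run = out$epochs_run, pools = out$pools,
                 kappa = kappa, seed = seed, config = config,
                 net_config = net_config),
            class = "xt_development")
}

#' @export
print.xt_development <- function(x, ...) {
  cat("<xt_development>\n")
  cat(sprintf("  kappa %.2f, seed %s: %d epoch(s), criterion %s\n",
              x$kappa, format(x$seed), x$epochs_run,
              if (x$criterion_met) "met" else "NOT met"))
  tl <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final train error %.3f, generalization error %.3f\n",
              tl$train_error, tl$generalization_error))
  invisible(x)
}
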