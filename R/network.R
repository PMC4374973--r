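#' Build an XT network
#'
#' Constructs the layered settling network: two stimulus input layers, Task
#' and Dimension Cue inputs, a Hidden layer modelling posterior cortical
#' pathways, a PFC layer with recurrent excitation and intrinsic
#' maintenance currents, and a Response layer under k = 1 lateral
#' inhibition.  All projections are complete (all-to-all) with weights
#' initialised from a seeded uniform distribution on `[0, init_w]` and
#' clipped to `[w_min, w_max]` thereafter.  Identical `(config, seed)`
#' pairs yield bit-identical networks.
#'
#' @param config an [xt_config()] list.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `xt_network`: a list with elements `config`,
#'   `weights` (named target x source matrices), `maintenance` (per-PFC-unit
#'   nonnegative currents), `noise_pending` (PFC net-input noise applied to
#'   the next settle only) and `seed`.
#' @examples
#' net <- build_xt_network(xt_config(), seed = 1)
#' dim(net$weights$pfc_resp)  # response x pfc
#' @export
build_xt_network <- function(config = xt_config(), seed = 1) {
  check_config(config)
  cfg <- config
  rmat <- function(nr, nc) matrix(runif(nr * nc, 0, cfg$init_w), nr, nc)
  weights <- with_seed(seed, {
    w <- list(
      in1_hid  = rmat(cfg$n_hidden, cfg$n_input),
      in2_hid  = rmat(cfg$n_hidden, cfg$n_input),
      task_hid = rmat(cfg$n_hidden, cfg$n_task),
      pfc_hid  = rmat(cfg$n_hidden, cfg$n_pfc),
      hid_resp = rmat(cfg$n_response, cfg$n_hidden),
      in1_resp = rmat(cfg$n_response, cfg$n_input),
      in2_resp = rmat(cfg$n_response, cfg$n_input),
      pfc_resp = rmat(cfg$n_response, cfg$n_pfc),
      resp_resp = resp_lateral_matrix(cfg),
      resp_hid = rmat(cfg$n_hidden, cfg$n_response),
      hid_pfc  = rmat(cfg$n_pfc, cfg$n_hidden),
      task_pfc = rmat(cfg$n_pfc, cfg$n_task),
      cue_pfc  = cue_topographic_matrix(cfg),
      pfc_pfc  = rmat(cfg$n_pfc, cfg$n_pfc))
    w
  })
  structure(list(config = cfg, weights = weights,
                 maintenance = numeric(cfg$n_pfc),
                 noise_pending = numeric(cfg$n_pfc),
                 seed = seed),
            class = "xt_network")
}

# Topographically organised Dimension-Cue input: each cue unit projects
# strongly onto its own pool of PFC units (n_pfc / n_cue each) and weakly
# elsewhere, so distinct cues install distinct PFC pools from the start.
# What those pools come to mean for behaviour (the dimension-banded
# PFC -> Response mapping) is learned over development.
cue_topographic_matrix <- function(cfg) {
  pool <- ((seq_len(cfg$n_pfc) - 1L) %/%
             max(1L, cfg$n_pfc %/% cfg$n_cue)) %% cfg$n_cue + 1L
  w <- matrix(runif(cfg$n_pfc * cfg$n_cue, 0, 0.2 * cfg$init_w),
              cfg$n_pfc, cfg$n_cue)
  strong <- cbind(seq_len(cfg$n_pfc), pool)
  w[strong] <- runif(cfg$n_pfc, 0.5, 0.9) * cfg$w_max
  w
}

# Fixed (non-learnable) lateral excitation between Response units sharing a
# feature column across dimensions: the model's stand-in for a shared
# verbal label ("red" ink and the word RED name the same response).
resp_lateral_matrix <- function(cfg) {
  n <- cfg$n_response
  lev <- feature_level(seq_len(n), cfg$n_features)
  m <- outer(lev, lev, "==") * cfg$resp_lateral
  diag(m) <- 0
  m
}

#' @export
print.xt_network <- function(x, ...) {
  cfg <- x$config
  cat("<xt_network>\n")
  cat(sprintf("  input %dx2, task %d, cue %d, hidden %d (k=%d), pfc %d (k=%d), response %d (k=%d)\n",
              cfg$n_input, cfg$n_task, cfg$n_cue, cfg$n_hidden, cfg$k_hidden,
              cfg$n_pfc, cfg$k_pfc, cfg$n_response, cfg$k_response))
  cat(sprintf("  maintained PFC units: %d; seed %s\n",
              sum(x$maintenance > 0), format(x$seed)))
  invisible(x)
}

#' Pooled lateral inhibition (k-winners-take-all)
#'
#' Places a shared inhibition level between the k-th and (k+1)-th largest
#' net inputs (ties broken by lowest index) and returns the resulting
#' logistic activations, so that at most `k_winners` units exceed the
#' active threshold while the rank order of activations preserves the rank
#' order of net inputs.  With `k_winners` equal to the vector length the
#' inhibition sits at its zero floor and no competition occurs.
#'
#' @param net_inputs finite numeric vector of net inputs.
#' @param k_winners maximum number of strongly active units.
#' @param gain,bias logistic activation parameters.
#' @return activation vector in `[0, 1]`.
#' @examples
#' apply_inhibition(c(3, 2, 1), 1)
#' @export
apply_inhibition <- function(net_inputs, k_winners, gain = 6, bias = 0.25) {
  if (!all(is.finite(net_inputs))) stop("net inputs must be finite")
  n <- length(net_inputs)
  if (k_winners < 1 || k_winners > n)
    stop("k_winners must satisfy 1 <= k <= length(net_inputs)")
  as.numeric(cpp_kwta(net_inputs, as.integer(k_winners), gain, bias))
}

#' Settle the network to a stable activation state
#'
#' Iterates cycles of net-input computation (including PFC recurrence,
#' maintenance currents and any pending destabilisation noise), pooled
#' inhibition, and a sigmoidal activation step of size `dt`, until the
#' largest elementwise activation change falls below `tol` or `max_cycles`
#' is reached.  The cycle count is the settling-time readout used as the
#' model's reaction time.
#'
#' @param net an `xt_network`.
#' @param in1,in2 clamped stimulus patterns (length `n_input`; default off).
#' @param task Task-layer pattern, or a task name/index.
#' @param cue Dimension-Cue pattern, or a dimension index (`NA` = off).
#' @param resp_clamp optional Response-layer clamp (outcome phase).
#' @param maint,pnoise override the network's maintenance currents and
#'   pending PFC noise (defaults use the network's own state).
#' @param rnoise optional constant noise added to Response-layer net
#'   inputs (neural tie-breaking during free-choice test sessions).
#' @return a list of class `xt_settle` with per-layer `activations`,
#'   `cycles` and `converged`.  Non-convergence is reported, not raised.
#' @export
settle <- function(net, in1 = NULL, in2 = NULL, task = NULL, cue = NULL,
                   resp_clamp = NULL, maint = NULL, pnoise = NULL,
                   rnoise = NULL) {
  stopifnot(inherits(net, "xt_network"))
  cfg <- net$config
  in1 <- expand_pattern(in1, cfg$n_input)
  in2 <- expand_pattern(in2, cfg$n_input)
  task <- expand_task(task, cfg)
  cue <- expand_cue(cue, cfg)
  maint <- maint %||% net$maintenance
  pnoise <- pnoise %||% net$noise_pending
  res <- cpp_settle(net$weights, cfg, in1, in2, task, cue, maint, pnoise,
                    resp_clamp, rnoise)
  structure(list(activations = list(hidden = as.numeric(res$hidden),
                                    pfc = as.numeric(res$pfc),
                                    response = as.numeric(res$response)),
                 cycles = res$cycles, label_cycles = res$label_cycles,
                 converged = res$converged),
            class = "xt_settle")
}

expand_pattern <- function(x, n) {
  if (is.null(x)) return(numeric(n))
  stopifnot(length(x) == n)
  as.numeric(x)
}

expand_task <- function(task, cfg) {
  if (is.null(task)) return(numeric(cfg$n_task))
  if (is.character(task)) task <- match(task, XT_TASKS)
  if (length(task) == 1) return(onehot(task, cfg$n_task))
  stopifnot(length(task) == cfg$n_task)
  as.numeric(task)
}

expand_cue <- function(cue, cfg) {
  if (is.null(cue) || (length(cue) == 1 && is.na(cue)))
    return(numeric(cfg$n_cue))
  if (length(cue) == 1) return(onehot(cue, cfg$n_cue))
  stopifnot(length(cue) == cfg$n_cue)
  as.numeric(cue)
}

#' Read the network's response
#'
#' Returns the single Response unit above the active threshold after
#' settling, or `NA` when no unit is active.  With `k_response = 1` at most
#' one unit can be active; exact ties are resolved in favour of the lowest
#' index by the inhibition rule.
#'
#' @param result an `xt_settle` result (or a numeric Response vector).
#' @param a_on active threshold (default 0.5).
#' @return 1-based response-unit id, or `NA_integer_`.
#' @export
read_response <- function(result, a_on = 0.5) {
  act <- if (inherits(result, "xt_settle")) result$activations$response
         else as.numeric(result)
  i <- which.max(act)
  if (length(i) == 0 || act[i] <= a_on) return(NA_integer_)
  as.integer(i)
}

#' Train the network on a single supervised trial
#'
#' Two-phase update: an expectation phase in which the network settles to
#' its own response, and an outcome phase with the target pattern clamped
#' on the Response layer.  Each learnable weight moves proportionally to
#' the difference of unit co-activation products between the two phases
#' and is re-clipped to `[w_min, w_max]`.  The gate and critic are not
#' touched.
#'
#' @param net an `xt_network`.
#' @param trial a list with elements `in1` (pattern), optional `in2`,
#'   `task` (name or index), `cue` (dimension index or `NA`) and `target`
#'   (1-based response-unit id).
#' @param learning_rate contrastive learning rate (default from config).
#' @return the updated network, with a `last` element recording the
#'   expectation-phase `response`, `correct` flag and `cycles`.
#' @export
learn_trial <- function(net, trial, learning_rate = NULL) {
  stopifnot(inherits(net, "xt_network"))
  cfg <- net$config
  if (is.null(trial$target)) stop("trial must carry a target response")
  lr <- learning_rate %||% cfg$lrate
  task_i <- trial$task %||% NA
  if (is.character(task_i)) task_i <- match(task_i, XT_TASKS)
  cue_i <- trial$cue %||% NA
  res <- cpp_run_trials(
    net$weights, cfg,
    matrix(expand_pattern(trial$in1, cfg$n_input), 1),
    matrix(expand_pattern(trial$in2, cfg$n_input), 1),
    as.integer(ifelse(is.na(task_i), -1, task_i - 1)),
    as.integer(ifelse(is.na(cue_i), -1, cue_i - 1)),
    as.integer(trial$target - 1),
    net$maintenance, numeric(cfg$n_pfc + 1), net$noise_pending,
    1.0, cfg$alpha, cfg$maintenance_gain, cfg$noise_sd, cfg$gate_floor,
    cfg$gate_power, cfg$delta_tol, lr, matrix(0, 1, cfg$n_pfc),
    TRUE, FALSE)
  net$weights <- res$weights
  net$noise_pending <- as.numeric(res$noise_pending)
  net$last <- list(response = ifelse(res$response[1] < 0, NA_integer_,
                                     res$response[1] + 1L),
                   correct = res$correct[1], cycles = res$cycles[1])
  net
}

#' Save or load a network snapshot
#'
#' Snapshots are written with R's native serialisation (version 3), a
#' single-file array container keyed by layer and projection names; the
#' round trip is bit-exact.
#'
#' @param net an `xt_network`.
#' @param path file path.
#' @return `read_network()` returns the network; `write_network()` returns
#'   `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "xt_network"))
  saveRDS(net, path, version = 3)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "xt_network"))
  net
}
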