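#' Network and gating configuration
#'
#' Assembles all substrate parameters in one list.  Defaults describe the
#' standard architecture: two 5-dimension x 4-feature stimulus input layers,
#' a 4-unit Task layer, a 5-unit Dimension Cue layer, a Hidden layer, a PFC
#' layer with a recurrent self-projection and intrinsic maintenance
#' currents, and a 5 x 4 Response layer under strong (k = 1) lateral
#' inhibition.
#'
#' @param n_dimensions stimulus dimensions (default 5).
#' @param n_features feature levels per dimension (default 4).
#' @param n_task number of developmental tasks / Task-layer units.
#' @param n_hidden,n_pfc Hidden and PFC layer sizes.
#' @param k_hidden,k_pfc,k_response k-winners-take-all limits per layer.
#' @param gain,bias logistic activation gain and bias.
#' @param dt activation step size per settling cycle.
#' @param dt_pfc slower activation step size for the PFC layer: top-down
#'   control builds gradually, which is what makes conflict trials slow.
#' @param tol settling convergence tolerance (max elementwise change).
#' @param max_cycles settling cycle budget.
#' @param a_on active threshold: a unit counts as "on" above this level.
#' @param w_min,w_max weight clipping bounds.
#' @param init_w upper bound of the uniform weight initialisation.
#' @param lrate contrastive learning rate for the supervised pathway.
#' @param lr_pfc_mult learning-rate multiplier for the PFC output and
#'   recurrent projections (prefrontal rule representations consolidate
#'   faster than the posterior feature pathways).
#' @param lr_direct_mult learning-rate multiplier for the direct
#'   stimulus-to-response projections (the slow posterior pathway).
#' @param resp_lateral fixed lateral excitation between Response units that
#'   share a feature column across dimensions (default 0; superseded by
#'   `resp_pooled`).
#' @param resp_pooled use grouped Response inhibition: units sharing a
#'   feature column pool their net input into one verbal-label coalition,
#'   coalitions compete winner-take-all, and the winning coalition's best
#'   unit is expressed.  This is what yields classic congruency effects.
#' @param gamma TD discount factor (trials are single-step, so its exact
#'   value is non-critical).
#' @param alpha critic learning rate.
#' @param maintenance_gain intrinsic maintenance current applied to active
#'   PFC units when the gate strengthens.
#' @param noise_sd scale of the seeded Gaussian PFC net-input noise injected
#'   on destabilisation (scaled further by the gate magnitude).
#' @param gate_floor minimum destabilisation magnitude (before kappa
#'   scaling) triggered by a failed, unrewarded trial.
#' @param resp_noise standard deviation of optional per-card
#'   Response-layer net-input noise during free-choice WCST
#'   administration (0 disables it).
#' @param kick_width number of PFC units receiving the destabilisation
#'   kick (positive-rectified largest noise components); 0 applies the
#'   full Gaussian noise vector.
#' @param noise_decay per-cycle decay of the destabilisation noise during
#'   settling: the noise acts as a transient kick and the recurrent
#'   attractor completes a coherent pattern.
#' @param gate_power exponent applied to the destabilisation magnitude:
#'   values above 1 make the release of maintained PFC patterns
#'   supralinearly sensitive to the dopamine signal.
#' @param delta_tol band around zero within which the TD error is treated
#'   as exactly zero (gate holds).
#' @param weak_dimension index of the under-trained ("colour naming")
#'   dimension.
#' @param strong_dimension index of the designated prepotent
#'   ("word reading") dimension.
#' @param proj_scales optional named numeric vector overriding the fixed
#'   relative net-input scale of individual projections (names
#'   `sc_in_hid`, `sc_task_hid`, `sc_pfc_hid`, `sc_resp_hid`,
#'   `sc_hid_resp`, `sc_pfc_resp`, `sc_hid_pfc`, `sc_task_pfc`,
#'   `sc_cue_pfc`, `sc_pfc_pfc`).  The defaults keep the single-unit Task and Dimension
#'   Cue inputs competitive with the much larger Hidden-layer projection
#'   at the PFC.
#' @return a named list of class `xt_config`.
#' @export
xt_config <- function(n_dimensions = 5, n_features = 4, n_task = 4,
                      n_hidden = 40, n_pfc = 20,
                      k_hidden = 10, k_pfc = 2, k_response = 1,
                      gain = 40, bias = 0.08, dt = 0.3, dt_pfc = 0.05,
                      tol = 1e-4,
                      max_cycles = 200, a_on = 0.5,
                      w_min = 0, w_max = 1, init_w = 0.25,
                      lrate = 0.005, lr_pfc_mult = 4, lr_direct_mult = 0.5,
                      resp_lateral = 0, resp_pooled = TRUE,
                      gamma = 0.9, alpha = 0.2,
                      maintenance_gain = 0.7, noise_sd = 1.2,
                      gate_floor = 0.5, gate_power = 2, noise_decay = 1.0,
                      resp_noise = 0, kick_width = 0, delta_tol = 1e-9,
                      weak_dimension = 5, strong_dimension = 4,
                      proj_scales = NULL) {
  cfg <- list(
    n_dimensions = as.integer(n_dimensions),
    n_features = as.integer(n_features),
    n_input = as.integer(n_dimensions * n_features),
    n_task = as.integer(n_task),
    n_cue = as.integer(n_dimensions),
    n_hidden = as.integer(n_hidden),
    n_pfc = as.integer(n_pfc),
    n_response = as.integer(n_dimensions * n_features),
    k_hidden = as.integer(k_hidden), k_pfc = as.integer(k_pfc),
    k_response = as.integer(k_response),
    gain = gain, bias = bias, dt = dt, dt_pfc = dt_pfc, tol = tol,
    max_cycles = as.integer(max_cycles), a_on = a_on,
    w_min = w_min, w_max = w_max, init_w = init_w,
    lrate = lrate, lr_pfc_mult = lr_pfc_mult,
    lr_direct_mult = lr_direct_mult, resp_lateral = resp_lateral,
    resp_pooled = isTRUE(resp_pooled),
    gamma = gamma, alpha = alpha,
    maintenance_gain = maintenance_gain, noise_sd = noise_sd,
    gate_floor = gate_floor, gate_power = gate_power,
    noise_decay = noise_decay, resp_noise = resp_noise,
    kick_width = as.integer(kick_width), delta_tol = delta_tol,
    weak_dimension = as.integer(weak_dimension),
    strong_dimension = as.integer(strong_dimension))
  scales <- c(sc_in_hid = 1.0, sc_task_hid = 1.0, sc_pfc_hid = 0.5,
              sc_resp_hid = 0.0, sc_hid_resp = 1.0, sc_pfc_resp = 2.0,
              sc_in_resp = 1.0,
              sc_hid_pfc = 0.4, sc_task_pfc = 1.0, sc_cue_pfc = 4.0,
              sc_pfc_pfc = 0.8)
  if (!is.null(proj_scales)) {
    bad <- setdiff(names(proj_scales), names(scales))
    if (length(bad)) stop("unknown projection scale(s): ",
                          paste(bad, collapse = ", "))
    scales[names(proj_scales)] <- proj_scales
  }
  cfg <- c(cfg, as.list(scales))
  class(cfg) <- "xt_config"
  check_config(cfg)
  cfg
}

check_config <- function(cfg) {
  need <- c("n_dimensions", "n_features", "n_input", "n_task", "n_cue",
            "n_hidden", "n_pfc", "n_response", "k_hidden", "k_pfc",
            "k_response", "gain", "bias", "dt", "dt_pfc", "tol", "max_cycles",
            "a_on", "w_min", "w_max", "init_w", "lrate", "lr_pfc_mult",
            "lr_direct_mult", "resp_lateral", "resp_pooled",
            "gamma", "alpha", "maintenance_gain", "noise_sd", "gate_floor",
            "gate_power", "noise_decay", "resp_noise", "kick_width", "delta_tol",
            "weak_dimension", "strong_dimension",
            "sc_in_hid", "sc_task_hid", "sc_pfc_hid", "sc_resp_hid",
            "sc_hid_resp", "sc_pfc_resp", "sc_in_resp", "sc_hid_pfc",
            "sc_task_pfc", "sc_cue_pfc", "sc_pfc_pfc")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration is missing required fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sizes <- c(cfg$n_input, cfg$n_task, cfg$n_cue, cfg$n_hidden, cfg$n_pfc,
             cfg$n_response)
  if (any(sizes < 1)) stop("all layer sizes must be >= 1", call. = FALSE)
  if (cfg$k_hidden < 1 || cfg$k_hidden > cfg$n_hidden ||
      cfg$k_pfc < 1 || cfg$k_pfc > cfg$n_pfc ||
      cfg$k_response < 1 || cfg$k_response > cfg$n_response)
    stop("k_winners must satisfy 1 <= k <= layer size", call. = FALSE)
  if (cfg$tol <= 0) stop("tol must be positive", call. = FALSE)
  if (cfg$gamma < 0 || cfg$gamma >= 1)
    stop("gamma must lie in [0, 1)", call. = FALSE)
  if (cfg$w_min >= cfg$w_max) stop("w_min must be < w_max", call. = FALSE)
  invisible(cfg)
}

#' Read or write a configuration as JSON
#'
#' @param cfg an `xt_config` list.
#' @param path file path.
#' @return `read_config()` returns an `xt_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- xt_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  ints <- c("n_dimensions", "n_features", "n_input", "n_task", "n_cue",
            "n_hidden", "n_pfc", "n_response", "k_hidden", "k_pfc",
            "k_response", "max_cycles", "weak_dimension", "strong_dimension")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  class(cfg) <- "xt_config"
  check_config(cfg)
  cfg
}
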