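#' Wisconsin Card Sorting Test configuration
#'
#' The standard 128-card administration: cards vary along three stimulus
#' dimensions with four feature levels each (64 unique cards, each
#' appearing twice), the hidden sorting rule switches after 10 consecutive
#' correct sorts, and the session ends after 6 completed categories or
#' when the deck is exhausted.
#'
#' @param n_dimensions card dimensions (fixed at 3 in the standard test).
#' @param n_features feature levels per dimension.
#' @param deck_size total cards (two passes over the unique cards).
#' @param streak_to_switch consecutive correct sorts ending a category.
#' @param categories_to_finish categories ending the session.
#' @param dimensions which network stimulus dimensions carry the card
#'   (default the first three; the remaining dimensions stay silent).
#' @return a list of class `xt_wcst_config`.
#' @export
wcst_config <- function(n_dimensions = 3, n_features = 4, deck_size = 128,
                        streak_to_switch = 10, categories_to_finish = 6,
                        dimensions = 1:3) {
  if (deck_size != 2 * n_features^n_dimensions)
    stop("deck_size must equal two passes over the unique cards")
  stopifnot(length(dimensions) == n_dimensions)
  structure(list(n_dimensions = as.integer(n_dimensions),
                 n_features = as.integer(n_features),
                 deck_size = as.integer(deck_size),
                 streak_to_switch = as.integer(streak_to_switch),
                 categories_to_finish = as.integer(categories_to_finish),
                 dimensions = as.integer(dimensions)),
            class = "xt_wcst_config")
}

#' Build a WCST deck
#'
#' Two seeded shuffles of the 64 unique three-dimension cards,
#' concatenated: 128 cards in which every unique feature combination
#' appears exactly twice.  Deterministic given the seed.
#'
#' @param config an [wcst_config()] list.
#' @param seed integer seed.
#' @return integer matrix with `deck_size` rows (cards in administration
#'   order) and one feature-level column per card dimension.
#' @export
build_deck <- function(config = wcst_config(), seed = 1) {
  cards <- factorial_stimuli(config$n_dimensions, config$n_features)
  n <- nrow(cards)
  ord <- with_seed(seed, c(sample.int(n), sample.int(n)))
  deck <- cards[ord, , drop = FALSE]
  rownames(deck) <- NULL
  deck
}

#' Score one WCST sort
#'
#' A sort is correct iff the response names the card's feature on the
#' current rule dimension; it is perseverative iff it is incorrect, a
#' previous rule exists, and the response names the card's feature on that
#' previous rule dimension.  Errors in the first category (no previous
#' rule) are never perseverative.
#'
#' @param card integer vector of the card's feature levels (one per card
#'   dimension).
#' @param response_feature 1-based response-unit id, or `NA` for no
#'   response.
#' @param current_rule,previous_rule card-dimension indices
#'   (`previous_rule = NA` in the first category).
#' @param config an [wcst_config()] list (supplies the mapping from card
#'   dimensions to network stimulus dimensions).
#' @return list with logical `correct` and `perseverative`.
#' @export
classify_response <- function(card, response_feature, current_rule,
                              previous_rule = NA,
                              config = wcst_config()) {
  nf <- config$n_features
  want <- feature_id(config$dimensions[current_rule], card[current_rule], nf)
  correct <- !is.na(response_feature) && response_feature == want
  persev <- FALSE
  if (!correct && !is.na(previous_rule)) {
    prev <- feature_id(config$dimensions[previous_rule], card[previous_rule],
                       nf)
    persev <- !is.na(response_feature) && response_feature == prev
  }
  list(correct = correct, perseverative = persev)
}

card_pattern <- function(card, config, n_input, n_features) {
  p <- numeric(n_input)
  p[feature_id(config$dimensions, card, n_features)] <- 1
  p
}

#' Administer the WCST to a trained network
#'
#' Follows the human protocol: each card is presented with the Dimension
#' Cue layer fully off, the network settles and names a feature, sparse
#' feedback (`r = 1` on a correct sort, 0 otherwise) drives the
#' kappa-scaled TD error, the critic learns, and the gate strengthens or
#' destabilises PFC maintenance.  Supervised learning is off: the only
#' information about the hidden rule is reward.  The rule switches after
#' `streak_to_switch` consecutive correct sorts (seeded random rule
#' sequence without immediate repetition) and the session ends at
#' `categories_to_finish` categories or deck exhaustion.
#'
#' @param net a trained `xt_network` (maintenance starts cleared).
#' @param critic the network's `xt_critic`; its `kappa` is the dopamine
#'   efficacy in force during the session.
#' @param config an [wcst_config()] list.
#' @param seed integer seed (deck order, rule sequence, gate noise).
#' @param critic_alpha critic learning rate in force during the session
#'   (default 0: the reward expectation consolidated over development is
#'   not relearned within a single administration).
#' @return an object of class `xt_wcst_session`: a per-card `trials` data
#'   frame (card features, rules, response, correct, perseverative, delta,
#'   gate action, settling cycles) plus the counters `total_errors`,
#'   `perseverative_errors`, `categories_completed`, `cards_administered`
#'   and a `no_response` diagnostic flag.
#' @export
administer_wcst <- function(net, critic, config = wcst_config(), seed = 1,
                            critic_alpha = 0) {
  stopifnot(inherits(net, "xt_network"), inherits(critic, "xt_critic"))
  critic$alpha <- critic_alpha
  cfg <- net$config
  with_seed(seed, {
    deck <- build_deck(config, seed = derive_seed(seed, 101))
    # seeded rule walk without immediate repetition
    n_rules_needed <- config$categories_to_finish + config$deck_size
    rules <- integer(n_rules_needed)
    rules[1] <- sample.int(config$n_dimensions, 1)
    for (i in 2:n_rules_needed)
      rules[i] <- sample(setdiff(seq_len(config$n_dimensions), rules[i - 1]), 1)
    net$maintenance <- numeric(cfg$n_pfc)
    net$noise_pending <- numeric(cfg$n_pfc)
    rule_i <- 1L
    streak <- 0L
    categories <- 0L
    rows <- vector("list", config$deck_size)
    for (tr in seq_len(config$deck_size)) {
      card <- deck[tr, ]
      res <- settle(net,
                    in1 = card_pattern(card, config, cfg$n_input,
                                       cfg$n_features),
                    task = "name_feature",
                    rnoise = rnorm(cfg$n_response, 0, cfg$resp_noise))
      resp <- read_response(res, cfg$a_on)
      prev <- if (rule_i > 1L) rules[rule_i - 1L] else NA_integer_
      cls <- classify_response(card, resp, rules[rule_i], prev, config)
      r <- as.numeric(cls$correct)
      pfc <- res$activations$pfc
      # value read as a reward probability, capped just below certainty so
      # a rewarded sort always yields a positive surprise that re-closes
      # the gate, and a rewarded streak is never destabilised by overshoot
      v <- min(0.95, max(0, compute_value(critic, pfc)))
      delta <- compute_td_error(r, v, 0, critic$gamma, critic$kappa)
      critic <- update_critic(critic, delta, pfc)
      sig <- classify_gate(delta, cfg$delta_tol, kappa = critic$kappa)
      net <- apply_gate(net, sig, pfc)
      rows[[tr]] <- data.frame(
        card = tr, rule = rules[rule_i], previous_rule = prev,
        response = resp, correct = cls$correct,
        perseverative = cls$perseverative, delta = delta,
        action = sig$action, cycles = res$cycles)
      if (cls$correct) {
        streak <- streak + 1L
        if (streak == config$streak_to_switch) {
          categories <- categories + 1L
          if (categories == config$categories_to_finish) {
            rows <- rows[seq_len(tr)]
            break
          }
          rule_i <- rule_i + 1L
          streak <- 0L
        }
      } else {
        streak <- 0L
      }
      if (tr == config$deck_size) rows <- rows[seq_len(tr)]
    }
    trials <- do.call(rbind, rows)
    structure(list(trials = trials,
                   total_errors = sum(!trials$correct),
                   perseverative_errors = sum(trials$perseverative),
                   categories_completed = categories,
                   cards_administered = nrow(trials),
                   no_response = all(is.na(trials$response)),
                   kappa = critic$kappa, seed = seed, config = config,
                   critic = critic),
              class = "xt_wcst_session")
  })
}

#' @export
print.xt_wcst_session <- function(x, ...) {
  p <- percent_scores(x)
  cat("<xt_wcst_session>\n")
  cat(sprintf("  kappa %.2f: %d cards, %d categories\n", x$kappa,
              x$cards_administered, x$categories_completed))
  cat(sprintf("  errors %d (%.2f%%), perseverative %d (%.2f%%)\n",
              x$total_errors, p[["pct_total_errors"]],
              x$perseverative_errors, p[["pct_perseverative_errors"]]))
  invisible(x)
}

#' Percentage error scores for a WCST session
#'
#' Both percentages use the cards administered in the session as the
#' denominator: `100 * errors / cards_administered`.
#'
#' @param session an `xt_wcst_session`.
#' @return named numeric vector with `pct_total_errors` and
#'   `pct_perseverative_errors`.
#' @export
percent_scores <- function(session) {
  stopifnot(inherits(session, "xt_wcst_session"))
  if (session$cards_administered <= 0)
    stop("session has no administered cards")
  c(pct_total_errors = 100 * session$total_errors / session$cards_administered,
    pct_perseverative_errors =
      100 * session$perseverative_errors / session$cards_administered)
}
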