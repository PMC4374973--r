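# WCST environment: deck, scoring, administration, invariants.

test_that("the deck is two shuffles of the 64 unique cards", {
  deck <- build_deck(seed = 1)
  expect_equal(nrow(deck), 128)
  key <- apply(deck, 1, paste, collapse = "-")
  expect_equal(sort(table(key))[[1]], 2)  # every combination exactly twice
  expect_equal(length(unique(key)), 64)
  expect_identical(deck, build_deck(seed = 1))
  expect_false(identical(deck, build_deck(seed = 2)))
  expect_true(all(deck >= 1 & deck <= 4))
})

test_that("sorts are scored by the current rule, perseveration by the previous", {
  card <- c(1, 3, 2)  # e.g. red, circle, two
  # correct sort under the shape rule
  r <- classify_response(card, feature_id(2, 3), current_rule = 2)
  expect_true(r$correct); expect_false(r$perseverative)
  # names the colour while shape is the rule, colour was the previous rule
  r2 <- classify_response(card, feature_id(1, 1), 2, previous_rule = 1)
  expect_false(r2$correct); expect_true(r2$perseverative)
  # first category: errors are never perseverative
  r3 <- classify_response(card, feature_id(1, 1), 2, previous_rule = NA)
  expect_false(r3$perseverative)
  # no response: incorrect, not perseverative
  r4 <- classify_response(card, NA, 2, previous_rule = 1)
  expect_false(r4$correct); expect_false(r4$perseverative)
})

test_that("scorer invariants hold over random response streams", {
  # scripted scorer harness: replay random responses through the same
  # classification and streak logic used by the administration loop
  run_stream <- function(responses, rules, config = wcst_config(),
                         deck = build_deck(seed = 2)) {
    rule_i <- 1; streak <- 0; cats <- 0; tot <- 0; per <- 0; n <- 0
    for (i in seq_len(nrow(deck))) {
      prev <- if (rule_i > 1) rules[rule_i - 1] else NA
      cls <- classify_response(deck[i, ], responses[i], rules[rule_i], prev)
      n <- n + 1
      if (!cls$correct) { tot <- tot + 1; streak <- 0 }
      if (cls$perseverative) per <- per + 1
      if (cls$correct) {
        streak <- streak + 1
        if (streak == config$streak_to_switch) {
          cats <- cats + 1
          if (cats == config$categories_to_finish) break
          rule_i <- rule_i + 1; streak <- 0
        }
      }
    }
    list(tot = tot, per = per, cats = cats, n = n)
  }
  rules <- rep(c(1, 2, 3), 5)
  set.seed(99)
  for (i in 1:25) {
    resp <- sample(c(NA, 1:12), 128, replace = TRUE)
    s <- run_stream(resp, rules)
    expect_lte(s$per, s$tot)
    expect_lte(s$tot, s$n)
    expect_lte(s$n, 128)
    expect_lte(s$cats, 6)
  }
})

test_that("a perfect rule-following agent finishes with errors only at switches", {
  config <- wcst_config()
  deck <- build_deck(config, seed = 4)
  rules <- c(2, 3, 1, 2, 1, 3)
  rule_i <- 1; streak <- 0; cats <- 0; err <- 0; n <- 0
  believed <- rules[1]  # oracle agent knows the first rule
  for (i in seq_len(nrow(deck))) {
    resp <- feature_id(config$dimensions[believed], deck[i, believed])
    cls <- classify_response(deck[i, ], resp, rules[rule_i],
                             if (rule_i > 1) rules[rule_i - 1] else NA, config)
    n <- n + 1
    if (!cls$correct) { err <- err + 1; streak <- 0; believed <- rules[rule_i] }
    else {
      streak <- streak + 1
      if (streak == config$streak_to_switch) {
        cats <- cats + 1
        if (cats == config$categories_to_finish) break
        rule_i <- rule_i + 1; streak <- 0
      }
    }
  }
  expect_equal(cats, 6)
  expect_lte(n, 128)
  expect_lte(err, 5)  # at most one informative error per unsignalled switch
})

test_that("rule switches happen exactly after ten consecutive correct sorts", {
  dev <- dev_control()
  cr <- dev$critic
  sess <- administer_wcst(dev$network, cr, seed = 21)
  tr <- sess$trials
  # wherever the logged rule changes, the preceding ten sorts were correct
  ch <- which(diff(tr$rule) != 0) # last index before each switch
  for (i in ch) {
    expect_true(all(tr$correct[(i - 9):i]))
    if (i >= 11) expect_false(all(tr$correct[(i - 10):i]))
  }
  # counters agree with a recount from the trial log
  expect_equal(sess$total_errors, sum(!tr$correct))
  expect_equal(sess$perseverative_errors, sum(tr$perseverative))
  expect_equal(sess$cards_administered, nrow(tr))
  expect_lte(sess$perseverative_errors, sess$total_errors)
  expect_lte(sess$cards_administered, 128)
  expect_lte(sess$categories_completed, 6)
  # session end condition
  expect_true(sess$categories_completed == 6 || sess$cards_administered == 128)
  # reproducibility
  sess2 <- administer_wcst(dev$network, cr, seed = 21)
  expect_identical(sess$trials, sess2$trials)
})

test_that("percentage scores use cards administered as the denominator", {
  dev <- dev_control()
  sess <- administer_wcst(dev$network, dev$critic, seed = 5)
  p <- percent_scores(sess)
  expect_equal(p[["pct_total_errors"]],
               100 * sess$total_errors / sess$cards_administered)
  expect_equal(p[["pct_perseverative_errors"]],
               100 * sess$perseverative_errors / sess$cards_administered)
  # Table-1-style self-consistency: counts recoverable from the percentages
  expect_equal(p[["pct_total_errors"]] * sess$cards_administered / 100,
               sess$total_errors)
})

test_that("gating is what enables flexibility: a weakened gate perseverates more", {
  dev <- dev_control()
  gated <- mean(sapply(1:4, function(s)
    administer_wcst(dev$network, dev$critic, seed = 30 + s)$perseverative_errors))
  # near-disabled release: strong dopamine attenuation freezes maintained
  # rules in place once established
  weak <- dev$critic; weak$kappa <- 0.3
  frozen <- mean(sapply(1:4, function(s)
    administer_wcst(dev$network, weak, seed = 30 + s)$perseverative_errors))
  expect_gt(frozen, gated)
})
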