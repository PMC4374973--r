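# Developmental curriculum: stimulus space, pools, trial sampling, the
# develop-to-criterion loop.

test_that("stimulus split partitions the space deterministically", {
  sp <- split_stimuli(seed = 3)
  expect_equal(length(sp$train) + length(sp$novel), 1024)
  expect_length(intersect(sp$train, sp$novel), 0)
  expect_identical(sp, split_stimuli(seed = 3))
  expect_false(identical(sp$novel, split_stimuli(seed = 4)$novel))
  # every individual feature appears in the training pool
  stim <- factorial_stimuli()
  counts <- apply(stim[sp$train, ], 2, tabulate, nbins = 4)
  expect_true(all(counts > 0))
})

test_that("relevant-dimension sampling honours the frequency manipulation", {
  cfg <- curriculum_config()
  set.seed(12)
  tr <- sample_trials(100000, cfg)
  freq <- tabulate(tr$cue, nbins = 5) / 100000
  expect_equal(freq[5], 0.25 / 4.25, tolerance = 0.01)  # ~0.0588
  expect_equal(freq[1], 1 / 4.25, tolerance = 0.01)

  # ratio 1: uniform (chi-squared not rejected at alpha = 0.01)
  cfg1 <- curriculum_config(weak_frequency_ratio = 1)
  set.seed(13)
  tr1 <- sample_trials(100000, cfg1)
  p <- suppressWarnings(stats::chisq.test(tabulate(tr1$cue, 5))$p.value)
  expect_gt(p, 0.01)
})

test_that("trial semantics match each task's definition", {
  cfg <- curriculum_config()
  stim <- factorial_stimuli()
  set.seed(21)
  tr <- sample_trials(4000, cfg)
  d <- tr$trials

  nm <- which(d$task == "name_feature")
  expect_equal(tr$target[nm],
               feature_id(d$dimension[nm], stim[d$s1[nm], ][cbind(seq_along(nm), d$dimension[nm])]))

  mt <- which(d$task == "match_feature")
  f1 <- stim[d$s1[mt], ]; f2 <- stim[d$s2[mt], ]
  shared <- f1 == f2
  expect_true(all(rowSums(shared) == 1))                     # share exactly one
  expect_true(all(shared[cbind(seq_along(mt), d$dimension[mt])]))
  expect_equal(tr$target[mt],
               feature_id(d$dimension[mt], f1[cbind(seq_along(mt), d$dimension[mt])]))

  cp <- which(d$task == "compare_feature")
  l1 <- stim[d$s1[cp], ][cbind(seq_along(cp), d$dimension[cp])]
  l2 <- stim[d$s2[cp], ][cbind(seq_along(cp), d$dimension[cp])]
  expect_true(all(l1 != l2))
  expect_equal(tr$target[cp], feature_id(d$dimension[cp], pmax(l1, l2)))

  cn <- which(d$task == "cued_name")
  expect_equal(rowSums(tr$in1[cn, , drop = FALSE]), rep(2, length(cn)))
  # two-stimulus tasks populate the second input; one-stimulus tasks do not
  expect_true(all(rowSums(tr$in2[c(nm, cn), , drop = FALSE]) == 0))
  expect_true(all(rowSums(tr$in2[c(mt, cp), , drop = FALSE]) == 5))
})

test_that("training trials never use novel-pool stimuli", {
  sp <- split_stimuli(seed = 5)
  set.seed(6)
  tr <- sample_trials(5000, curriculum_config(), pool = sp$train)
  used <- c(tr$trials$s1, tr$trials$s2)
  used <- used[!is.na(used)]
  expect_length(intersect(used, sp$novel), 0)
})

test_that("generalization evaluation logs the requested trials", {
  net <- build_xt_network(xt_config(), seed = 2)
  sp <- split_stimuli(seed = 2)
  err <- evaluate_generalization(net, sp$novel, n_trials = 100, seed = 9)
  expect_gte(err, 0); expect_lte(err, 1)
  expect_equal(attr(err, "n_trials"), 100)
  expect_length(attr(err, "correct"), 100)
  # untrained network: near-chance (no response or a near-arbitrary unit)
  expect_gt(err, 0.5)
  # determinism under the same seed
  expect_equal(as.numeric(err),
               as.numeric(evaluate_generalization(net, sp$novel, 100, seed = 9)))
})

test_that("development reaches criterion, logs every epoch, and reproduces", {
  dev <- dev_control()
  expect_true(dev$criterion_met)
  expect_lte(dev$epochs_run, 100)
  expect_equal(nrow(dev$trace), dev$epochs_run)
  expect_true(all(dev$trace$epoch == seq_len(dev$epochs_run)))
  expect_lte(dev$trace$generalization_error[dev$epochs_run], 0.10)
  # generalization error trends downward over development
  expect_lt(cor(dev$trace$epoch, dev$trace$generalization_error,
                method = "spearman"), 0)
  # identical seed reproduces the whole run bit-for-bit
  dev2 <- run_development(kappa = 1, seed = dev$seed,
                          config = curriculum_config())
  expect_identical(dev$network$weights, dev2$network$weights)
  expect_identical(dev$trace, dev2$trace)
})
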