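# Experiment orchestration: statistics, selectivity, reproducibility.

test_that("two-group F matches hand computation and the t-squared identity", {
  f <- anova_f(c(1, 2, 3), c(4, 5, 6))
  expect_equal(f$F, 13.5)
  expect_equal(f$df1, 1L); expect_equal(f$df2, 4L)

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(9, mean = runif(1))
    f <- anova_f(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p, tt$p.value, tolerance = 1e-10)
  }
  # zero within-group variance with equal means
  expect_equal(anova_f(c(1, 1), c(1, 1))$F, 0)
  expect_error(anova_f(1, c(1, 2)), "at least 2")
})

test_that("dimensional selectivity is 0 for uniform and 1 for banded weights", {
  uni <- matrix(0.5, 20, 20)
  expect_equal(dimensional_selectivity(uni), 0)
  banded <- matrix(0, 20, 20)
  for (j in 1:20) banded[feature_id(((j - 1) %% 5) + 1, 1:4), j] <- 0.7
  expect_equal(dimensional_selectivity(banded), 1)
  # invariant to overall rescaling
  set.seed(3)
  w <- matrix(runif(400), 20, 20)
  expect_equal(dimensional_selectivity(w), dimensional_selectivity(10 * w))
  expect_error(dimensional_selectivity(matrix(0, 20, 20)), "zero")
  expect_error(dimensional_selectivity(-uni), "nonnegative")
})

test_that("selectivity increases over development", {
  dev <- dev_control()
  early <- build_xt_network(dev$net_config, seed = xtgate:::derive_seed(dev$seed, 1))
  expect_gt(dimensional_selectivity(dev$network$weights$pfc_resp),
            dimensional_selectivity(early$weights$pfc_resp))
})

test_that("group experiments are reproducible and probe-isolated", {
  e1 <- run_group_experiment(n_per_group = 2, master_seed = 5,
                             stroop_n_per_cell = 4)
  e2 <- run_group_experiment(n_per_group = 2, master_seed = 5,
                             stroop_n_per_cell = 4)
  expect_identical(e1$per_network, e2$per_network)
  expect_equal(nrow(e1$per_network), 4)
  expect_true(all(c("total_errors", "perseverative_errors",
                    "pct_total_errors", "pct_perseverative_errors",
                    "stroop_interference") %in% names(e1$per_network)))
  expect_equal(unique(e1$comparison$df1), 1L)
  expect_equal(unique(e1$comparison$df2), 2L)
})

test_that("developmental probes do not perturb the developing network", {
  hashes <- list()
  probe <- function(net, critic, epoch) {
    before <- serialize(list(net$weights, critic$weights), NULL)
    sess <- administer_wcst(net, critic, seed = 1)
    st <- run_stroop(net, build_stroop_block(2, seed = 1))
    after <- serialize(list(net$weights, critic$weights), NULL)
    hashes[[length(hashes) + 1]] <<- identical(before, after)
    c(ok = 1)
  }
  dev <- run_development(kappa = 1, seed = 41,
                         config = curriculum_config(max_epochs = 2),
                         stop_at_criterion = FALSE,
                         probe = probe, probe_every = 1)
  expect_length(dev$probes, 2)
  expect_true(all(unlist(hashes)))
  # probes leave the run's outcome identical to an unprobed run
  dev0 <- run_development(kappa = 1, seed = 41,
                          config = curriculum_config(max_epochs = 2),
                          stop_at_criterion = FALSE)
  expect_identical(dev$network$weights, dev0$network$weights)
  expect_identical(dev$trace, dev0$trace)
})

test_that("null experiments give well-behaved p-values", {
  # both groups at kappa = 1 in posthoc mode share development, so the
  # WCST outcomes differ only through seeded administrations
  e <- run_group_experiment(n_per_group = 3, kappas = c(1, 1),
                            master_seed = 11, stroop_n_per_cell = 2)
  persev <- e$comparison[e$comparison$measure == "perseverative_errors", ]
  expect_gt(persev$p, 0.01)
})
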