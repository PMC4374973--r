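# Substrate: construction, inhibition, settling, learning.

test_that("network construction is deterministic and validates its config", {
  n1 <- build_xt_network(xt_config(), seed = 1)
  n2 <- build_xt_network(xt_config(), seed = 1)
  expect_identical(n1$weights, n2$weights)
  n3 <- build_xt_network(xt_config(), seed = 2)
  expect_false(identical(n1$weights, n3$weights))

  expect_equal(n1$config$n_input, 20)  # 5 dimensions x 4 feature levels
  expect_equal(dim(n1$weights$hid_resp), c(20, 40))
  expect_equal(dim(n1$weights$pfc_pfc), c(20, 20))

  bad <- xt_config()
  bad$n_response <- NULL
  expect_error(build_xt_network(bad, seed = 1), "missing")
  expect_error(xt_config(k_pfc = 50), "k_winners")
  expect_error(xt_config(tol = 0), "tol")
})

test_that("inhibition matches an exhaustive oracle on small integer inputs", {
  gain <- 40; bias <- 0.08; a_on <- 0.5
  # oracle: stable top-k membership characterises the active set exactly
  # (for integer inputs the boundary gap is 0 or >= 1 >> 2*bias)
  oracle_active <- function(net, k) {
    n <- length(net)
    if (k >= n) return(net - bias > 0)
    ord <- order(-net, seq_len(n))  # stable: ties to lowest index
    top <- ord[seq_len(k)]
    nk <- net[ord[k]]; nk1 <- net[ord[k + 1]]
    act <- rep(FALSE, n)
    if (nk > nk1 || nk > 0) act[top] <- TRUE  # decisive or boosted winners
    else act <- net > bias                    # boundary tie at the floor
    act
  }
  vals <- 0:3
  for (n in 2:5) {
    grids <- do.call(expand.grid, rep(list(vals), n))
    for (k in 1:n) {
      for (r in seq_len(nrow(grids))) {
        net <- as.numeric(grids[r, ])
        a <- apply_inhibition(net, k, gain, bias)
        expect_true(all(a >= 0 & a <= 1))
        expect_lte(sum(a > a_on), k)
        expect_identical(a > a_on, oracle_active(net, k))
        # rank order preserved among strictly ordered pairs
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
          if (net[i] > net[j]) expect_gte(a[i], a[j])
        }
      }
    }
  }
})

test_that("inhibition tie and degenerate cases follow the documented rules", {
  a <- apply_inhibition(c(3, 2, 1), 1, gain = 40, bias = 0.08)
  expect_equal(sum(a > 0.5), 1)
  expect_equal(which.max(a), 1L)
  # all equal, k = 1: lowest index wins
  a2 <- apply_inhibition(c(2, 2, 2), 1, gain = 40, bias = 0.08)
  expect_equal(which(a2 > 0.5), 1L)
  # k = length: inhibition at floor, orderings preserved
  a3 <- apply_inhibition(c(0.3, 0.1, 0.2), 3, gain = 40, bias = 0.08)
  expect_true(a3[1] > a3[3] && a3[3] > a3[2])
  expect_error(apply_inhibition(c(1, Inf), 1), "finite")
  expect_error(apply_inhibition(c(1, 2), 0), "k_winners")
})

test_that("settling matches an independent fixed-point iteration oracle", {
  # two-unit toy: only in1 -> hidden carries signal; all else silent
  cfg <- xt_config(n_hidden = 2, n_pfc = 2, n_task = 1,
                   k_hidden = 1, k_pfc = 1, resp_pooled = FALSE)
  net <- build_xt_network(cfg, seed = 1)
  for (nm in names(net$weights)) net$weights[[nm]][] <- 0
  net$weights$in1_hid[1, 1] <- 0.9
  net$weights$in1_hid[2, 1] <- 0.4
  in1 <- c(1, rep(0, cfg$n_input - 1))
  res <- settle(net, in1 = in1)

  # oracle: direct iteration of the documented update equations
  sig <- function(z) 1 / (1 + exp(-z))
  x <- rep(sig(-cfg$gain * cfg$bias), 2)
  for (c in 1:cfg$max_cycles) {
    netin <- c(0.9, 0.4) * cfg$sc_in_hid  # hidden net input, constant here
    thr <- mean(netin)                    # k=1 midpoint between the units
    tgt <- sig(cfg$gain * (netin - thr - cfg$bias))
    xn <- x + cfg$dt * (tgt - x)
    if (max(abs(xn - x)) < cfg$tol) { x <- xn; break }
    x <- xn
  }
  expect_equal(res$activations$hidden, x, tolerance = 1e-6)
  expect_true(res$converged)
})

test_that("settling respects clamping, bounds, and the resting state", {
  cfg <- tiny_config()
  net <- build_xt_network(cfg, seed = 3)
  # zero weights, zero input: resting fixed point within two cycles
  net0 <- net
  for (nm in names(net0$weights)) net0$weights[[nm]][] <- 0
  r0 <- settle(net0)
  expect_lte(r0$cycles, 2)
  expect_true(r0$converged)

  # clamped response stays fixed; activations stay in [0, 1]
  clamp <- onehot_vec <- numeric(cfg$n_response); clamp[4] <- 1
  set.seed(5)
  stim <- as.numeric(runif(cfg$n_input) < 0.25)
  r1 <- settle(net, in1 = stim, task = 1, resp_clamp = clamp)
  expect_identical(r1$activations$response, clamp)
  for (l in r1$activations) expect_true(all(l >= 0 & l <= 1))

  # determinism
  r2 <- settle(net, in1 = stim, task = 1, resp_clamp = clamp)
  expect_identical(r1, r2)
})

test_that("maintained PFC units stay active through settling", {
  dev <- dev_control()
  net <- dev$network
  s0 <- settle(net, cue = 2, task = "name_feature")
  patt <- s0$activations$pfc > 0.5
  expect_gt(sum(patt), 0)
  maint <- ifelse(patt, net$config$maintenance_gain, 0)
  # no contradictory input: maintained units persist without the cue
  s1 <- settle(net, task = "name_feature", maint = maint,
               pnoise = numeric(net$config$n_pfc))
  expect_true(all(s1$activations$pfc[patt] > 0.5))
})

test_that("learning reduces error on repeated trials and honours edge cases", {
  cfg <- xt_config()
  net <- build_xt_network(cfg, seed = 9)
  trial <- list(in1 = {p <- numeric(cfg$n_input); p[c(1, 6)] <- 1; p},
                task = "cued_name", cue = 1, target = 1)
  # learning_rate = 0 leaves the network unchanged
  net0 <- learn_trial(net, trial, learning_rate = 0)
  expect_identical(net0$weights, net$weights)

  # when the expectation phase already produces the target, no change
  dev <- dev_control()
  tn <- dev$network
  s <- settle(tn, in1 = trial$in1, task = trial$task, cue = trial$cue,
              maint = numeric(20), pnoise = numeric(20))
  if (identical(read_response(s), 1L)) {
    tn$maintenance <- numeric(20); tn$noise_pending <- numeric(20)
    tn2 <- learn_trial(tn, trial)
    for (nm in names(tn2$weights))
      expect_equal(tn2$weights[[nm]], tn$weights[[nm]], tolerance = 1e-4)
  }

  # repeated training on one naming trial: error monotonically non-increasing
  err <- numeric(20)
  n2 <- net
  for (i in 1:20) {
    n2 <- learn_trial(n2, trial)
    err[i] <- as.numeric(!isTRUE(n2$last$correct))
  }
  expect_true(all(diff(err) <= 0))
})

test_that("responses are read out as the single active unit", {
  act <- numeric(20); act[7] <- 0.9
  expect_identical(read_response(act), 7L)
  expect_identical(read_response(numeric(20)), NA_integer_)
  expect_identical(read_response(rep(0.4, 20)), NA_integer_)
})

test_that("network snapshots round-trip bit-exactly", {
  net <- build_xt_network(xt_config(), seed = 4)
  net$maintenance[3] <- 0.25
  p <- tempfile(fileext = ".rds")
  write_network(net, p)
  net2 <- read_network(p)
  expect_identical(net, net2)
  unlink(p)
})
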