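#' One-way two-group ANOVA F
#'
#' Between-group mean square over within-group mean square, with
#' `df1 = 1`, `df2 = n_a + n_b - 2`.  Identical to the square of the
#' pooled two-sample t statistic.  Zero within-group variance with equal
#' means gives `F = 0`.
#'
#' @param group_a,group_b numeric outcome vectors (each length >= 2).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_f <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  gm <- mean(c(group_a, group_b))
  ssb <- na * (mean(group_a) - gm)^2 + nb * (mean(group_b) - gm)^2
  ssw <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  df1 <- 1L; df2 <- na + nb - 2L
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  list(F = f, df1 = df1, df2 = df2, p = p)
}

# One-tailed paired t test that b > a (same networks, two conditions).
t_one_tailed_paired <- function(a, b) {
  d <- b - a
  n <- length(d)
  se <- sd(d) / sqrt(n)
  if (se == 0) return(list(t = 0, p = if (mean(d) > 0) 0 else 1))
  t <- mean(d) / se
  list(t = t, p = pt(t, n - 1, lower.tail = FALSE))
}

# One-tailed two-sample pooled t test that group_b > group_a.
t_one_tailed <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  sp2 <- (sum((group_a - mean(group_a))^2) +
          sum((group_b - mean(group_b))^2)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) return(list(t = 0, p = if (mean(group_b) > mean(group_a)) 0 else 1))
  t <- (mean(group_b) - mean(group_a)) / se
  list(t = t, p = pt(t, na + nb - 2, lower.tail = FALSE))
}

#' Dimensional selectivity of PFC output weights
#'
#' Operationalises the banded structure of PFC-to-Response weights: for
#' each PFC unit, the fraction of its total outgoing weight mass landing
#' on its single best dimension's row of Response units, averaged over
#' units and rescaled so that uniform weights give 0 and one-dimension-only
#' weights give 1.  Invariant to overall weight rescaling.
#'
#' @param weights nonnegative PFC-to-Response matrix (response x pfc, rows
#'   grouped by dimension).
#' @param n_dimensions,n_features Response-layer layout.
#' @return selectivity index in `[0, 1]`.
#' @export
dimensional_selectivity <- function(weights, n_dimensions = 5,
                                    n_features = 4) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("all-zero weight matrix")
  stopifnot(nrow(weights) == n_dimensions * n_features)
  dims <- feature_dim(seq_len(nrow(weights)), n_features)
  mass <- rowsum(weights, dims)          # dimension x pfc
  tot <- colSums(mass)
  use <- tot > 0
  frac <- apply(mass[, use, drop = FALSE], 2, max) / tot[use]
  mean((frac - 1 / n_dimensions) / (1 - 1 / n_dimensions))
}

wcst_measures <- function(session) {
  p <- percent_scores(session)
  c(total_errors = session$total_errors,
    pct_total_errors = unname(p["pct_total_errors"]),
    perseverative_errors = session$perseverative_errors,
    pct_perseverative_errors = unname(p["pct_perseverative_errors"]),
    categories = session$categories_completed,
    cards = session$cards_administered)
}

#' Group comparison experiment
#'
#' Treats each trained network as an individual participant.  In
#' `"posthoc"` mode, `n_per_group` networks are developed once under
#' normal dopamine modulation (kappa = 1) and each is then tested twice —
#' once per kappa value applied at test, the dopamine reduction introduced
#' only after standard development.  In `"developmental"` mode separate
#' groups develop with their kappa in force from the beginning.  Every
#' network is administered the full WCST and a Stroop block, and a one-way
#' F is computed per measure across the two groups.
#'
#' @param n_per_group networks per group.
#' @param kappas length-2 vector: control then reduced dopamine efficacy.
#' @param mode `"posthoc"` or `"developmental"`.
#' @param master_seed seed governing the whole experiment.
#' @param config,net_config curriculum and network configurations.
#' @param dev_epochs optional cap on `max_epochs` (scaled runs).
#' @param stroop_n_per_cell Stroop trials per cell.
#' @return an object of class `xt_group_experiment`: `per_network` (one
#'   row per network per group with the four WCST measures and Stroop
#'   interference) and `comparison` (per-measure group means, F, dfs, p).
#' @export
run_group_experiment <- function(n_per_group = 10, kappas = c(1.00, 0.54),
                                 mode = c("posthoc", "developmental"),
                                 master_seed = 1,
                                 config = curriculum_config(),
                                 net_config = xt_config(),
                                 dev_epochs = NULL,
                                 stroop_n_per_cell = 16) {
  mode <- match.arg(mode)
  stopifnot(n_per_group >= 2, length(kappas) == 2,
            all(kappas > 0 & kappas <= 1))
  if (!is.null(dev_epochs)) config$max_epochs <- as.integer(dev_epochs)
  groups <- c("healthy", "autism")
  rows <- list()
  devs <- list()
  if (mode == "posthoc") {
    for (i in seq_len(n_per_group))
      devs[[i]] <- run_development(kappa = 1, seed = derive_seed(master_seed, i),
                                   config = config, net_config = net_config)
  }
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      dev <- if (mode == "posthoc") devs[[i]]
             else run_development(kappa = kappas[g],
                                  seed = derive_seed(master_seed, 1000 * g + i),
                                  config = config, net_config = net_config)
      critic <- dev$critic
      critic$kappa <- kappas[g]
      wseed <- derive_seed(master_seed, 5000 + 100 * g + i)
      sess <- administer_wcst(dev$network, critic, seed = wseed)
      blk <- build_stroop_block(stroop_n_per_cell,
                                seed = derive_seed(master_seed, 7000 + i))
      st <- run_stroop(dev$network, blk)
      m <- wcst_measures(sess)
      rows[[length(rows) + 1]] <- data.frame(
        group = groups[g], kappa = kappas[g], network = i,
        criterion_met = dev$criterion_met, t(m),
        stroop_interference = stroop_interference(st, "weak"),
        stroop_interference_strong = stroop_interference(st, "strong"))
    }
  }
  per_network <- do.call(rbind, rows)
  measures <- c("total_errors", "pct_total_errors", "perseverative_errors",
                "pct_perseverative_errors", "stroop_interference")
  comparison <- do.call(rbind, lapply(measures, function(m) {
    a <- per_network[per_network$group == "healthy", m]
    b <- per_network[per_network$group == "autism", m]
    f <- anova_f(a, b)
    data.frame(measure = m, healthy = mean(a), autism = mean(b),
               F = f$F, df1 = f$df1, df2 = f$df2, p = f$p)
  }))
  structure(list(per_network = per_network, comparison = comparison,
                 mode = mode, kappas = kappas, master_seed = master_seed),
            class = "xt_group_experiment")
}

#' @export
print.xt_group_experiment <- function(x, ...) {
  cat(sprintf("<xt_group_experiment> mode=%s, kappas=%.2f/%.2f, n=%d/group\n",
              x$mode, x$kappas[1], x$kappas[2],
              sum(x$per_network$group == "healthy")))
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Developmental-trajectory study
#'
#' Two groups develop for the full `epochs` epochs (no early stop), one
#' with normal dopamine modulation and one with reduced modulation in
#' force from the very beginning.  After every `probe_every`-th epoch a
#' frozen clone of each network is probed on the WCST, a Stroop block and
#' the PFC dimensional-selectivity index; the developing network is never
#' perturbed by a probe.  Per-epoch one-tailed t tests compare the groups.
#'
#' @param n_per_group networks per group (default 10).
#' @param kappas length-2 vector, control then reduced.
#' @param epochs developmental period (default 100).
#' @param probe_every epoch interval between probes.
#' @param master_seed seed governing the study.
#' @param config,net_config curriculum and network configurations.
#' @param stroop_n_per_cell Stroop trials per probe cell.
#' @return an object of class `xt_developmental_study`: `trace` (one row
#'   per network per probed epoch with WCST, Stroop and selectivity
#'   measures) and `epoch_tests` (per-epoch group means and one-tailed p
#'   for perseverative errors and Stroop interference).
#' @export
run_developmental_study <- function(n_per_group = 10, kappas = c(1.00, 0.54),
                                    epochs = 100, probe_every = 1,
                                    master_seed = 1,
                                    config = curriculum_config(),
                                    net_config = xt_config(),
                                    stroop_n_per_cell = 16) {
  config$max_epochs <- as.integer(epochs)
  groups <- c("healthy", "autism")
  rows <- list()
  for (g in 1:2) {
    for (i in seq_len(n_per_group)) {
      probe_fun <- local({
        g_ <- g; i_ <- i
        function(net, critic, epoch) {
          wseed <- derive_seed(master_seed, 20000 + 570 * g_ + 31 * i_ + epoch)
          sess <- administer_wcst(net, critic, seed = wseed)
          blk <- build_stroop_block(stroop_n_per_cell,
                                    seed = derive_seed(master_seed, 30000 + epoch))
          st <- run_stroop(net, blk)
          sel <- dimensional_selectivity(net$weights$pfc_resp,
                                         net$config$n_dimensions,
                                         net$config$n_features)
          c(wcst_measures(sess),
            stroop_interference = stroop_interference(st, "weak"),
            selectivity = sel)
        }
      })
      dev <- run_development(kappa = kappas[g],
                             seed = derive_seed(master_seed, 1000 * g + i),
                             config = config, net_config = net_config,
                             stop_at_criterion = FALSE,
                             probe = probe_fun, probe_every = probe_every)
      for (ep in names(dev$probes)) {
        epi <- as.integer(ep)
        gen <- dev$trace$generalization_error[dev$trace$epoch == epi]
        rows[[length(rows) + 1]] <- data.frame(
          group = groups[g], kappa = kappas[g], network = i, epoch = epi,
          generalization_error = gen, t(dev$probes[[ep]]))
      }
    }
  }
  trace <- do.call(rbind, rows)
  eps <- sort(unique(trace$epoch))
  epoch_tests <- do.call(rbind, lapply(eps, function(ep) {
    sub <- trace[trace$epoch == ep, ]
    a <- sub[sub$group == "healthy", ]
    b <- sub[sub$group == "autism", ]
    tp <- t_one_tailed(a$perseverative_errors, b$perseverative_errors)
    ts <- t_one_tailed(a$stroop_interference, b$stroop_interference)
    data.frame(epoch = ep,
               persev_healthy = mean(a$perseverative_errors),
               persev_autism = mean(b$perseverative_errors),
               persev_p = tp$p,
               stroop_healthy = mean(a$stroop_interference),
               stroop_autism = mean(b$stroop_interference),
               stroop_p = ts$p,
               selectivity_healthy = mean(a$selectivity),
               selectivity_autism = mean(b$selectivity))
  }))
  structure(list(trace = trace, epoch_tests = epoch_tests,
                 kappas = kappas, master_seed = master_seed),
            class = "xt_developmental_study")
}

#' Kappa grid search
#'
#' Develops `n_seeds` networks at every kappa on the grid (the reduction
#' in force throughout development, as in the original parameter search),
#' administers the WCST to each, and summarises mean perseverative errors
#' and the criterion-failure rate per kappa, together with a Spearman
#' monotonicity statistic.
#'
#' @param grid kappa values in `(0, 1]`.
#' @param n_seeds networks per grid point.
#' @param master_seed seed governing the sweep.
#' @param config,net_config curriculum and network configurations.
#' @return an object of class `xt_kappa_sweep`: `per_network` rows,
#'   a `summary` table (kappa, mean perseverative errors, failure rate)
#'   and `spearman_rho` between kappa and mean perseverative errors.
#' @export
kappa_sweep <- function(grid = seq(0.5, 1.0, by = 0.1), n_seeds = 10,
                        master_seed = 1,
                        config = curriculum_config(),
                        net_config = xt_config()) {
  stopifnot(all(grid > 0 & grid <= 1))
  rows <- list()
  for (k in seq_along(grid)) {
    for (i in seq_len(n_seeds)) {
      dev <- run_development(kappa = grid[k],
                             seed = derive_seed(master_seed, 100 * k + i),
                             config = config, net_config = net_config)
      critic <- dev$critic
      sess <- administer_wcst(dev$network, critic,
                              seed = derive_seed(master_seed, 9000 + 100 * k + i))
      rows[[length(rows) + 1]] <- data.frame(
        kappa = grid[k], seed = i, criterion_met = dev$criterion_met,
        epochs = dev$epochs_run,
        perseverative_errors = sess$perseverative_errors,
        total_errors = sess$total_errors)
    }
  }
  per_network <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_network, per_network$kappa),
    function(s) data.frame(kappa = s$kappa[1],
                           mean_perseverative = mean(s$perseverative_errors),
                           mean_total = mean(s$total_errors),
                           failure_rate = mean(!s$criterion_met))))
  rownames(summary) <- NULL
  rho <- suppressWarnings(cor(summary$kappa, summary$mean_perseverative,
                              method = "spearman"))
  structure(list(per_network = per_network, summary = summary,
                 spearman_rho = rho, master_seed = master_seed),
            class = "xt_kappa_sweep")
}

#' @export
print.xt_kappa_sweep <- function(x, ...) {
  cat("<xt_kappa_sweep>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("  Spearman rho(kappa, perseverative errors) = %.3f\n",
              x$spearman_rho))
  invisible(x)
}
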