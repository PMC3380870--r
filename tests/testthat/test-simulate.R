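test_that("scenario validation rejects infeasible settings", {
  expect_error(sim_scenario(3, 10, n_edges = 4), "infeasible")
  expect_error(sim_scenario(3, 10, alpha = 0.6, beta = 0.5), "alpha")
  expect_silent(sim_scenario(3, 10, n_edges = 3))
})

test_that("sampled ground truths have the requested structure", {
  set.seed(401)
  sc0 <- sim_scenario(5, 20, n_edges = 0)
  expect_equal(sample_nem(sc0)$graph, identity_graph(sprintf("S%02d", 1:5)))

  sc <- sim_scenario(11, 50, n_edges = 11)
  for (i in 1:10) {
    tr <- sample_nem(sc)
    expect_equal(sum(tr$graph) - 11, 11)  # exact edge count off-diagonal
    a <- tr$graph; diag(a) <- 0
    # acyclic: the adjacency is nilpotent
    expect_equal(sum(Reduce(`%*%`, rep(list(a), 11))), 0)
  }
  # true prior rows are the unit vectors of the attachment
  tr <- sample_nem(sc)
  tgt <- unclass(tr$attachment)
  expect_true(all(tr$prior_star[cbind(seq_along(tgt),
                                      ifelse(is.na(tgt), 12L, tgt))] == 1))
  expect_equal(sum(is.na(tgt)), round(0.2 * 50))
})

test_that("effects attach uniformly across signals", {
  set.seed(411)
  sc <- sim_scenario(5, 10000, n_edges = 4, null_fraction = 0)
  tgt <- unclass(sample_nem(sc)$attachment)
  expect_gt(chisq.test(table(tgt))$p.value, 1e-4)
})

test_that("the alpha/beta noise model produces the optimal-test log odds", {
  set.seed(421)
  sc <- sim_scenario(4, 5000, n_edges = 3, alpha = 0.05, beta = 0.1,
                     null_fraction = 0.2)
  tr <- sample_nem(sc)
  r <- generate_logodds(tr)
  pos <- log(0.9 / 0.05); neg <- log(0.1 / 0.95)
  expect_equal(pos, 2.8904, tolerance = 1e-4)
  expect_equal(neg, -2.2513, tolerance = 1e-4)
  expect_true(all(r %in% c(pos, neg)))
  f <- t(predict_effects(tr$graph, tr$attachment))  # E x S
  frac_pos_on <- mean(r[f == 1] == pos)
  frac_pos_off <- mean(r[f == 0] == pos)
  n_on <- sum(f == 1)
  expect_lt(abs(frac_pos_on - 0.9), 4 * sqrt(0.9 * 0.1 / n_on))
  expect_lt(abs(frac_pos_off - 0.05), 0.01)
})

test_that("edge sensitivity and specificity count off-diagonal positions", {
  labs <- paste0("S", 1:3)
  truth <- identity_graph(labs)
  truth[1, 2] <- truth[2, 3] <- 1
  expect_equal(unname(evaluate_edges(truth, truth)), c(1, 1))
  est0 <- identity_graph(labs)
  expect_equal(unname(evaluate_edges(est0, truth)), c(0, 1))
  # 1 of 2 true edges found plus 1 false positive among 4 true negatives
  est <- identity_graph(labs)
  est[1, 2] <- 1; est[3, 1] <- 1
  expect_equal(unname(evaluate_edges(est, truth)), c(0.5, 0.75))
  # no true edges: sensitivity undefined
  expect_true(is.na(evaluate_edges(est0, identity_graph(labs))[["sensitivity"]]))
})

test_that("the normalized prior distance behaves as a [0, 1] metric", {
  set.seed(431)
  sc <- sim_scenario(3, 6, n_edges = 2)
  tr <- sample_nem(sc)
  expect_equal(prior_l1(tr$prior_star, tr), 0)
  unif <- uniform_prior(names(tr$attachment), rownames(tr$graph))
  # uniform over 4 targets vs a unit vector: L1 = 1.5, normalized 0.75
  expect_equal(prior_l1(unif, tr), 0.75, tolerance = 1e-12)
  for (i in 1:5) {
    nu <- matrix(runif(6 * 4), 6, 4); nu <- nu / rowSums(nu)
    d <- prior_l1(attachment_prior(nu, rownames(tr$graph),
                                   names(tr$attachment)), tr)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("the posterior quantile separates informative from flat posteriors", {
  set.seed(441)
  labs <- paste0("S", 1:3)
  # flat case: zero data scores all graphs equally; strict comparison -> 0
  r0 <- log_odds(matrix(0, 5, 3), signal_labels = labs)
  nu0 <- uniform_prior(rownames(r0), labs)
  g <- identity_graph(labs)
  expect_equal(posterior_quantile(g, r0, nu0, 0.5, n_random = 200L), 0)

  # noiseless data with the true deterministic prior: truth at the maximum
  # (S large enough that a random draw virtually never duplicates the truth,
  # which would not count as strictly below)
  inst <- noiseless_instance(6, 60, n_edges = 5)
  expect_equal(posterior_quantile(inst$truth$graph, inst$r,
                                  inst$truth$prior_star, 0.5,
                                  n_random = 500L), 1)
})

test_that("the benchmark table covers every scenario, method and replicate", {
  set.seed(451)
  sc <- sim_scenario(4, 60, n_edges = 3, alpha = 0.001, beta = 0.001)
  cfg <- mc_eminem_config(n_steps = 150L, burn_in = 50L, thin = 5L,
                          max_rounds = 2L)
  out <- tempfile()
  res <- run_benchmark(list(sc), methods = c("mc_eminem", "em_only",
                                             "random_sampling",
                                             "exhaustive"),
                       n_replicates = 2L, seed = 3L, config = cfg,
                       outdir = out)
  expect_equal(nrow(res), 8L)
  expect_true(all(c("sensitivity", "specificity", "runtime_s") %in%
                  names(res)))
  # noiseless: the exhaustive MAP and MC EMiNEM recover the truth
  expect_equal(res$sensitivity[res$method == "exhaustive"], c(1, 1))
  expect_equal(res$sensitivity[res$method == "mc_eminem"], c(1, 1))
  summ <- attr(res, "summary")
  expect_equal(nrow(summ), 4L)
  expect_true(file.exists(file.path(out, "benchmark_results.tsv")))
  expect_true(file.exists(file.path(out, "benchmark_summary.tsv")))
  expect_error(run_benchmark(list(sim_scenario(5, 10)),
                             methods = "exhaustive", n_replicates = 1L),
               "S > 4")
})

test_that("benchmark replicates are reproducible under a fixed seed", {
  sc <- sim_scenario(3, 30, n_edges = 2, alpha = 0.01, beta = 0.01)
  cfg <- mc_eminem_config(n_steps = 100L, burn_in = 50L, thin = 5L,
                          max_rounds = 1L)
  r1 <- run_benchmark(list(sc), methods = "mc_eminem", n_replicates = 2L,
                      seed = 11L, config = cfg)
  r2 <- run_benchmark(list(sc), methods = "mc_eminem", n_replicates = 2L,
                      seed = 11L, config = cfg)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_identical(r1$specificity, r2$specificity)
})
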