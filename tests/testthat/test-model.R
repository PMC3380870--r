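test_that("predicted effects follow the two-step-path semantics", {
  g <- signals_graph(diag(2), labels = c("s1", "s2"))
  a <- effects_attachment(c(1L, NA), signal_labels = c("s1", "s2"),
                          effect_labels = c("e1", "e2"))
  f <- predict_effects(g, a)
  expect_equal(f[, "e1"], c(s1 = 1, s2 = 0))
  # null-attached effects are always predicted inactive
  expect_equal(f[, "e2"], c(s1 = 0, s2 = 0))

  g2 <- signals_graph(matrix(c(1, 0, 1, 1), 2, 2), labels = c("s1", "s2"))
  a2 <- effects_attachment(2L, signal_labels = c("s1", "s2"),
                           effect_labels = "e1")
  expect_equal(predict_effects(g2, a2)[, "e1"], c(s1 = 1, s2 = 1))
})

test_that("prediction matrix equals the indicator of (Gamma Theta) >= 1", {
  set.seed(11)
  for (i in 1:20) {
    S <- sample(2:5, 1); E <- sample(1:8, 1)
    labs <- paste0("S", seq_len(S))
    g <- matrix(rbinom(S * S, 1, 0.5), S, S, dimnames = list(labs, labs))
    diag(g) <- 1
    tgt <- sample(c(seq_len(S), NA), E, replace = TRUE)
    a <- effects_attachment(tgt, signal_labels = labs)
    th <- matrix(0, S, E)
    th[cbind(tgt[!is.na(tgt)], which(!is.na(tgt)))] <- 1
    expect_equal(unname(predict_effects(g, a)), unname((g %*% th >= 1) * 1))
  }
})

test_that("predict_effects rejects mismatched labels", {
  g <- signals_graph(diag(2), labels = c("s1", "s2"))
  a <- effects_attachment(1L, signal_labels = c("x1", "x2"))
  expect_error(predict_effects(g, a), "labels")
})

test_that("log posterior marginalizes the attachment as computed by hand", {
  # S = 1, E = 1, nu = (1/2, 1/2), R = ln 3: marginal = log(0.5*3 + 0.5*1)
  g <- signals_graph(matrix(1), labels = "s1")
  r <- log_odds(matrix(log(3)), effect_labels = "e1", signal_labels = "s1")
  nu <- attachment_prior(matrix(c(0.5, 0.5), 1), signal_labels = "s1")
  expect_equal(log_posterior(g, r, nu, 0.5), log(2), tolerance = 1e-12)
})

test_that("with all-zero data, score differences come only from the edge prior", {
  set.seed(21)
  S <- 3
  labs <- paste0("S", 1:3)
  r <- log_odds(matrix(0, 4, S), signal_labels = labs)
  nu <- uniform_prior(rownames(r), labs)
  ep <- matrix(runif(S * S, 0.2, 0.8), S, S)
  gs <- enumerate_graphs(labs)
  sc <- vapply(gs, log_posterior, numeric(1), r = r, nu = nu, ep = ep)
  edges <- vapply(gs, oracle_edge_term, numeric(1), ep = ep)
  # attachment term is log(sum of a stochastic row) = 0 for every graph
  expect_equal(sc, edges, tolerance = 1e-12)
})

test_that("log posterior matches brute-force enumeration of all attachments", {
  set.seed(31)
  for (i in 1:10) {
    S <- sample(2:3, 1); E <- sample(2:4, 1)
    inst <- rand_instance(S, E)
    expect_equal(log_posterior(inst$g, inst$r, inst$nu, inst$ep),
                 oracle_log_posterior(inst$g, inst$r, inst$nu, inst$ep),
                 tolerance = 1e-8)
  }
})

test_that("an edge towards positively responding effects never hurts the score", {
  set.seed(41)
  labs <- paste0("S", 1:3)
  for (i in 1:10) {
    r <- matrix(rnorm(5 * 3, sd = 1.5), 5, 3)
    r[, 1] <- abs(r[, 1]) + 0.1  # every effect responds to perturbing S1
    r <- log_odds(r, signal_labels = labs)
    nu <- uniform_prior(rownames(r), labs)
    g <- matrix(rbinom(9, 1, 0.5), 3, 3, dimnames = list(labs, labs))
    diag(g) <- 1
    g[1, 2] <- 0
    g2 <- g; g2[1, 2] <- 1
    # uniform edge prior 0.5: the edge term is graph-independent, so the
    # score difference is the attachment-term difference
    expect_gte(log_posterior(g2, r, nu, 0.5), log_posterior(g, r, nu, 0.5))
  }
})

test_that("attachment posterior matches hand calculations and direct arithmetic", {
  # uniform prior, zero data -> uniform responsibilities
  labs <- c("s1", "s2")
  g <- identity_graph(labs)
  r0 <- log_odds(matrix(0, 1, 2), signal_labels = labs)
  nu <- uniform_prior("e1", labs)
  expect_equal(unname(attachment_posterior(g, r0, nu)[1, ]), rep(1 / 3, 3))

  # S = 1: omega = (0.5*3, 0.5) normalized = (0.75, 0.25)
  g1 <- signals_graph(matrix(1), labels = "s1")
  r1 <- log_odds(matrix(log(3)), signal_labels = "s1")
  nu1 <- attachment_prior(matrix(c(0.5, 0.5), 1), signal_labels = "s1")
  expect_equal(unname(attachment_posterior(g1, r1, nu1)[1, ]),
               c(0.75, 0.25), tolerance = 1e-12)

  # deterministic null prior wins regardless of the data
  nu_null <- attachment_prior(matrix(c(0, 0, 1), 1), signal_labels = labs)
  r_big <- log_odds(matrix(c(50, 50), 1), signal_labels = labs)
  expect_equal(unname(attachment_posterior(g, r_big, nu_null)[1, ]),
               c(0, 0, 1))

  # log-space result equals direct normalization on well-scaled inputs
  set.seed(51)
  for (i in 1:10) {
    inst <- rand_instance(3, 6)
    om <- attachment_posterior(inst$g, inst$r, inst$nu)
    w <- inst$nu * cbind(exp(inst$r %*% inst$g), 1)
    expect_equal(unname(om), unname(w / rowSums(w)), tolerance = 1e-9)
    expect_equal(rowSums(om), rep(1, nrow(om)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("attachment posterior rejects an all-zero prior row", {
  labs <- c("s1", "s2")
  g <- identity_graph(labs)
  r <- log_odds(matrix(0, 1, 2), signal_labels = labs)
  nu <- matrix(c(0, 0, 0), 1, dimnames = list("e1", c(labs, null_label())))
  expect_error(attachment_posterior(g, r, nu), "all-zero")
})

test_that("effects without strictly positive evidence are filtered out", {
  r <- log_odds(rbind(c(-1.2, -0.3), c(-1.2, 0.0), c(-1.2, 0.7)),
                effect_labels = c("a", "b", "c"),
                signal_labels = c("s1", "s2"))
  f <- filter_effects(r)
  expect_equal(names(f$kept), "c")
  expect_equal(nrow(f$logodds), 1L)
  expect_warning(filter_effects(r[1:2, , drop = FALSE]), "filtered")
})

test_that("filtering leaves the posterior ranking of graphs unchanged", {
  set.seed(61)
  labs <- paste0("S", 1:3)
  r <- matrix(rnorm(8 * 3, sd = 2), 8, 3)
  r[c(2, 5), ] <- -abs(r[c(2, 5), ])  # two effects with no positive entry
  r <- log_odds(r, signal_labels = labs)
  rf <- filter_effects(r)$logodds
  gs <- enumerate_graphs(labs)
  score_full <- function(g) log_posterior(g, r, uniform_prior(rownames(r), labs), 0.4)
  score_filt <- function(g) log_posterior(g, rf, uniform_prior(rownames(rf), labs), 0.4)
  sf <- vapply(gs, score_full, numeric(1))
  sr <- vapply(gs, score_filt, numeric(1))
  # all-negative effects can only discourage edges, never create them:
  # the maximizing graph is unchanged
  expect_equal(which.max(sf), which.max(sr))
})

test_that("mutually linked signals are merged transitively", {
  labs <- paste0("s", 1:3)
  r <- log_odds(matrix(rnorm(6), 2, 3), signal_labels = labs)

  g <- identity_graph(labs)
  g["s2", "s3"] <- g["s3", "s2"] <- 1
  m <- merge_indistinguishable(g, r)
  expect_equal(nrow(m$graph), 2L)
  expect_true("s2s3" %in% rownames(m$graph))
  expect_equal(m$logodds[, "s2s3"],
               rowMeans(r[, c("s2", "s3")]), ignore_attr = TRUE)

  # no mutual pair: unchanged
  g2 <- identity_graph(labs); g2["s1", "s2"] <- 1
  m2 <- merge_indistinguishable(g2, r)
  expect_equal(m2$graph, g2)

  # chained mutual pairs collapse into one node
  g3 <- identity_graph(labs)
  g3["s1", "s2"] <- g3["s2", "s1"] <- 1
  g3["s2", "s3"] <- g3["s3", "s2"] <- 1
  m3 <- merge_indistinguishable(g3, r)
  expect_equal(nrow(m3$graph), 1L)
  expect_equal(rownames(m3$graph), "s1s2s3")
})

test_that("merge groups equal the transitive closure of the mutual-edge relation", {
  set.seed(71)
  for (i in 1:10) {
    S <- sample(3:6, 1)
    labs <- paste0("s", seq_len(S))
    g <- matrix(rbinom(S * S, 1, 0.5), S, S, dimnames = list(labs, labs))
    diag(g) <- 1
    r <- log_odds(matrix(rnorm(2 * S), 2, S), signal_labels = labs)
    m <- merge_indistinguishable(g, r)
    # oracle: boolean closure of the symmetric mutual-edge relation
    mut <- (g == 1 & t(g) == 1)
    diag(mut) <- TRUE
    repeat {
      nxt <- (mut %*% mut) > 0
      if (identical(nxt, mut)) break
      mut <- nxt
    }
    oracle_groups <- unique(apply(mut, 1, function(z) paste(labs[z], collapse = "")))
    expect_setequal(rownames(m$graph), oracle_groups)
  }
})

test_that("constructors validate their invariants", {
  expect_error(signals_graph(matrix(c(1, 2, 0, 1), 2, 2)), "0 or 1")
  expect_error(signals_graph(matrix(1, 2, 3)), "square")
  expect_error(check_signals_graph({g <- diag(2); g[1, 1] <- 0; g}),
               "diagonal")
  expect_error(log_odds(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(attachment_prior(matrix(c(0.7, 0.7, 0.1), 1),
                                signal_labels = c("a", "b")), "sum to 1")
  expect_error(log_posterior(identity_graph(c("a", "b")),
                             log_odds(matrix(0, 1, 2),
                                      signal_labels = c("a", "b")),
                             uniform_prior("e1", c("a", "b")), ep = 1.2),
               "strictly in")
})
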