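# Structure-learning agent: CRP prior, task-set inference, policies, motor
# biases, Bayesian updates, and whole-block simulation.

test_that("CRP prior follows popularity and concentration", {
  p <- agent_params(alpha = 2)
  e <- new_expert("color")
  # first-ever context: all mass on a new task-set
  expect_equal(unname(crp_prior(e, "c1", p)), 1)
  observe_context(e, "c1", p)
  # one existing task-set with popularity 1, alpha = 2
  pr <- crp_prior(e, "c2", p)
  expect_equal(unname(pr), c(1 / 3, 2 / 3))
  expect_distribution(pr)
  # two task-sets with popularities 1 and 1, alpha = 2
  e3 <- new_expert("color", n_features = 3L)
  observe_context(e3, "c1", p)
  observe_context(e3, "c2", p)
  e3$P[2, ] <- c(0, 1, 0)  # second context committed to its own task-set
  pr3 <- crp_prior(e3, "c3", p)
  expect_equal(unname(pr3), c(1 / 4, 1 / 4, 1 / 2))
  # a known context is a contract violation
  expect_error(crp_prior(e, "c1", p), "already known")
})

test_that("task-set inference is MAP with lowest-id tie-break", {
  e <- new_expert("color")
  e$ctx_seen <- c(TRUE, TRUE)
  e$n_ts <- 2L
  e$P[1, ] <- c(0.7, 0.3)
  e$P[2, ] <- c(0.5, 0.5)
  expect_equal(infer_taskset(e, "c1"), 1L)
  expect_equal(infer_taskset(e, "c2"), 1L)  # tie -> lowest id
  # MAP is stable after a correct outcome under the MAP task-set
  p <- agent_params(routing = "none")
  before <- e$P[1, 1]
  update_expert(e, "c1", "s1", 2L, 1L, p, Z_map = 1L)
  expect_gte(e$P[1, 1], before)
  expect_equal(infer_taskset(e, "c1"), 1L)
})

test_that("expert policy is the lapse-mixed softmax of expected outcome", {
  p <- agent_params(epsilon = 0.1, beta = 30, routing = "none")
  e <- new_expert("color")
  observe_context(e, "c1", p)
  # no data: all expected outcomes equal -> uniform policy
  expect_equal(expert_policy(e, 1L, "s1", p), rep(0.25, 4))
  # planted counts: check against an independently computed formula
  e$succ[1, 1, ] <- c(8, 0, 1, 0)
  e$fail[1, 1, ] <- c(0, 6, 2, 3)
  q <- (e$succ[1, 1, ] + 1) / (e$succ[1, 1, ] + e$fail[1, 1, ] + 2)
  manual <- 0.9 * exp(30 * q) / sum(exp(30 * q)) + 0.1 / 4
  expect_equal(expert_policy(e, 1L, "s1", p), manual, tolerance = 1e-12)
  expect_distribution(manual)
  # large beta, no lapse: point mass on the argmax
  p2 <- agent_params(epsilon = 0, beta = 400, routing = "none")
  expect_equal(expert_policy(e, 1L, "s1", p2), c(1, 0, 0, 0),
               tolerance = 1e-10)
})

test_that("adjacency bias spreads the other stimulus's policy to neighbors", {
  p <- agent_params(epsilon = 0, beta = 60)
  e <- new_expert("color")
  observe_context(e, "c1", p)
  # other stimulus strongly mapped to F1 -> bias is a point mass on F2
  e$succ[1, 2, 1] <- 50; e$fail[1, 2, c(2, 3, 4)] <- 50
  expect_equal(adjacency_bias(e, 1L, "s1", p), c(0, 1, 0, 0),
               tolerance = 1e-9)
  # other stimulus on F2 -> half each on F1 and F3
  e2 <- new_expert("color")
  observe_context(e2, "c1", p)
  e2$succ[1, 2, 2] <- 50; e2$fail[1, 2, c(1, 3, 4)] <- 50
  expect_equal(adjacency_bias(e2, 1L, "s1", p), c(0.5, 0, 0.5, 0),
               tolerance = 1e-9)
  # uniform other-stimulus policy -> kernel column sums / 4
  e3 <- new_expert("color")
  observe_context(e3, "c1", p)
  expect_equal(adjacency_bias(e3, 1L, "s1", p),
               c(0.125, 0.375, 0.375, 0.125))
})

test_that("adjacency bias equals direct kernel summation on random policies", {
  set.seed(11)
  p <- agent_params()
  for (i in 1:25) {
    e <- new_expert("color")
    observe_context(e, "c1", p)
    e$succ[1, 2, ] <- rpois(4, 3)
    e$fail[1, 2, ] <- rpois(4, 3)
    pi_other <- expert_policy(e, 1L, "s2", agent_params(routing = "none"))
    b <- adjacency_bias(e, 1L, "s1", agent_params(routing = "none"))
    expect_equal(b, oracle_adjacency_bias(pi_other), tolerance = 1e-12)
    expect_distribution(b)
  }
})

test_that("symmetry bias counts symmetric completions in thirds", {
  p <- agent_params()
  e <- new_expert("color")
  observe_context(e, "c1", p)
  observe_context(e, "c2", p)
  e$P[2, ] <- c(0, 1)  # second context on its own task-set
  # nothing learned about the other task-set -> uniform
  expect_equal(symmetry_bias(e, 1L, "s1", "c1", p), rep(0.25, 4))
  # other task-set maps the same stimulus to F2: of the three symmetric
  # completions, two place the current stimulus on F1 and one on F4
  e$succ[2, 1, 2] <- 1
  expect_equal(symmetry_bias(e, 1L, "s1", "c1", p), c(2 / 3, 0, 0, 1 / 3))
  # edge position F4 known: completions split 1/3 on F2, 2/3 on F3
  e2 <- new_expert("color")
  observe_context(e2, "c1", p); observe_context(e2, "c2", p)
  e2$P[2, ] <- c(0, 1)
  e2$succ[2, 1, 4] <- 1
  expect_equal(symmetry_bias(e2, 1L, "s1", "c1", p), c(0, 1 / 3, 2 / 3, 0))
})

test_that("symmetry bias is a distribution for random knowledge states", {
  set.seed(21)
  p <- agent_params()
  for (i in 1:40) {
    e <- new_expert("color")
    observe_context(e, "c1", p); observe_context(e, "c2", p)
    e$P[2, ] <- c(0, 1)
    # random subset of cells known at random positions
    for (z in 1:2) for (s in 1:2) {
      if (runif(1) < 0.5) e$succ[z, s, sample.int(4, 1)] <- 1
    }
    b <- symmetry_bias(e, 1L, paste0("s", sample.int(2, 1)), "c1", p)
    expect_distribution(b)
  }
})

test_that("biased prediction mixes biases with weight f, only under prediction routing", {
  # fresh expert: p_beta = 0.5 everywhere; adjacency bias a point mass
  mk <- function(routing, f = 0.1, sym = FALSE) {
    p <- agent_params(f = f, routing = routing, bias_symmetry = sym,
                      epsilon = 0, beta = 60)
    e <- new_expert("color")
    observe_context(e, "c1", p)
    e$succ[1, 2, 1] <- 50; e$fail[1, 2, c(2, 3, 4)] <- 50  # others -> F1
    list(e = e, p = p)
  }
  s <- mk("prediction_and_policy")
  pred <- biased_prediction(s$e, 1L, "s1", s$p, context = "c1")
  expect_equal(pred[[2]], 0.9 * 0.5 + 0.1 * 1, tolerance = 1e-9)
  # f = 0: identity
  s0 <- mk("prediction_and_policy", f = 0)
  expect_equal(biased_prediction(s0$e, 1L, "s1", s0$p, context = "c1"),
               rep(0.5, 4))
  # policy-only routing leaves predictions unbiased
  sp <- mk("policy_only")
  expect_equal(biased_prediction(sp$e, 1L, "s1", sp$p, context = "c1"),
               rep(0.5, 4))
  # both biases enabled: even mixture of the two bias distributions
  sb <- mk("prediction_and_policy", sym = TRUE)
  adj <- adjacency_bias(sb$e, 1L, "s1", sb$p)
  sym <- symmetry_bias(sb$e, 1L, "s1", "c1", sb$p)
  expect_equal(biased_prediction(sb$e, 1L, "s1", sb$p, context = "c1"),
               0.9 * 0.5 + 0.1 * (adj + sym) / 2, tolerance = 1e-12)
})

test_that("action choice samples the reliability-weighted expert mixture", {
  p <- agent_params()
  a <- new_agent(p)
  set.seed(5)
  ch <- choose_action(a, "c1", "s1")
  expect_distribution(ch$pi)
  expect_equal(ch$pi, a$w * ch$pi_color + (1 - a$w) * ch$pi_shape)
  # degenerate weight: mixture equals the color expert's policy
  a$w <- 1
  ch2 <- choose_action(a, "c1", "s2")
  expect_equal(ch2$pi, ch2$pi_color)
  # identical expert policies: mixture equals either
  b <- new_agent(p)
  b$w <- 0.5
  ch3 <- choose_action(b, "c2", "s2")
  expect_equal(ch3$pi_color, ch3$pi_shape, tolerance = 1e-12)
  expect_equal(ch3$pi, ch3$pi_color, tolerance = 1e-12)
})

test_that("expert update applies Bayes rule and beta counting", {
  p <- agent_params(routing = "none")
  e <- new_expert("color")
  observe_context(e, "c1", p)
  observe_context(e, "c2", p)
  # flat likelihoods (no data): posterior unchanged by an outcome
  prior <- e$P[2, ]
  update_expert(e, "c2", "s1", 3L, 1L, p)
  expect_equal(e$P[2, ], prior)
  # Laplace rule: Beta(1,1) plus one success predicts 2/3
  z <- infer_taskset(e, "c2")
  expect_equal(biased_prediction(e, z, "s1", p, action = 3L), 2 / 3)
  # rows of P remain distributions
  expect_distribution(e$P[2, seq_len(e$n_ts)])
})

test_that("credit spreading deposits fractional counts on neighbors", {
  p <- agent_params(routing = "none", credit_spread = TRUE,
                    credit_weight = 0.1)
  e <- new_expert("color")
  observe_context(e, "c1", p)
  update_expert(e, "c1", "s1", 2L, 1L, p, Z_map = 1L)
  # full count on the pressed finger for the seen stimulus
  expect_equal(e$succ[1, 1, ], c(0, 1, 0, 0))
  # g / 2 pseudo-successes on F1 and F3 for the task-set's other stimulus
  expect_equal(e$succ[1, 2, ], c(0.05, 0, 0.05, 0))
  expect_equal(sum(e$fail), 0)
})

test_that("mixture update is Bayes with a likelihood floor", {
  a <- new_agent(agent_params())
  update_mixture(a, 0.3, 0.3)
  expect_equal(a$w, 0.5)
  update_mixture(a, 0.2, 0.1)
  expect_equal(a$w, 2 / 3)
  # repeated equal likelihoods leave w fixed
  b <- new_agent(agent_params())
  for (i in 1:20) update_mixture(b, 0.7, 0.7)
  expect_equal(b$w, 0.5)
  # zero likelihoods are floored, not NaN
  d <- new_agent(agent_params())
  update_mixture(d, 0, 0)
  expect_equal(d$w, 0.5)
  expect_true(is.finite(d$w))
})

test_that("block runs are reproducible and expose valid state", {
  p <- agent_params()
  sq <- generate_trial_sequence(80, seed = 2)
  b1 <- run_block(p, fixture_view("P1"), sq, seed = 9)
  b2 <- run_block(p, fixture_view("P1"), sq, seed = 9)
  expect_identical(b1$trials, b2$trials)
  expect_equal(b1$final_w_C, b2$final_w_C)
  expect_true(all(b1$w_trajectory >= 0 & b1$w_trajectory <= 1))
  for (e in list(b1$agent$color, b1$agent$shape)) {
    for (ci in which(e$ctx_seen)) {
      expect_distribution(e$P[ci, seq_len(e$n_ts)])
    }
    expect_true(all(e$succ >= 0) && all(e$fail >= 0))
  }
  # mismatched sequence and assignment
  bad <- sq
  bad$color <- "c9"
  expect_error(run_block(p, fixture_view("P1"), bad), "absent")
})

test_that("late-block accuracy approaches the lapse-limited bound", {
  # learned contingencies cap accuracy near 1 - epsilon * 3/4
  p <- agent_params()
  accs <- vapply(1:15, function(s) {
    sq <- generate_trial_sequence(120, seed = 100 + s)
    b <- run_block(p, fixture_view("P1"), sq, seed = 200 + s)
    mean(b$trials$correct[91:120])
  }, numeric(1))
  expect_gt(mean(accs), 0.8)
  expect_lte(mean(accs), 1 - 0.1 * 3 / 4 + 0.04)
})

test_that("exchanging dimension roles mirrors the mixture weight exactly", {
  p <- agent_params()
  sq <- generate_trial_sequence(80, seed = 31)
  v <- fixture_view("P3")
  vx <- exchange_dimensions(v)
  # relabel the sequence the same way: (ci, sj) -> (cj, si)
  sqx <- sq
  sqx$color <- paste0("c", substr(sq$shape, 2, 2))
  sqx$shape <- paste0("s", substr(sq$color, 2, 2))
  sqx$stimulus <- paste0(sqx$color, ".", sqx$shape)
  b <- run_block(p, v, sq, seed = 77)
  bx <- run_block(p, vx, sqx, seed = 77)
  expect_equal(bx$w_trajectory, 1 - b$w_trajectory, tolerance = 1e-9)
  expect_equal(bx$trials$action, b$trials$action)
})

test_that("an unbiased agent is indifferent between structures on average", {
  p <- agent_params(routing = "none")
  w <- vapply(1:60, function(s) {
    sq <- generate_trial_sequence(80, seed = 500 + s)
    run_block(p, fixture_view("P1"), sq, seed = 900 + s)$final_w_C
  }, numeric(1))
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 0.5), 3 * se + 0.02)
})

test_that("beta-count estimates converge to true outcome rates", {
  # fixed random policy stream against a fixed assignment
  set.seed(71)
  p <- agent_params(routing = "none")
  e <- new_expert("color")
  observe_context(e, "c1", p)
  true_rate <- c(0.8, 0.3, 0.55, 0.1)
  n <- 3000
  acts <- sample.int(4L, n, replace = TRUE)
  rews <- as.integer(runif(n) < true_rate[acts])
  for (t in seq_len(n)) {
    update_expert(e, "c1", "s1", acts[[t]], rews[[t]], p, Z_map = 1L)
  }
  est <- (e$succ[1, 1, ] + 1) / (e$succ[1, 1, ] + e$fail[1, 1, ] + 2)
  expect_equal(est, true_rate, tolerance = 0.06)
})
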