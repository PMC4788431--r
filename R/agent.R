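# Bayesian mixture-of-experts structure-learning agent.
#
# Two "experts" each commit to one hierarchical reading of the task: the
# color expert treats color as the context cueing a task-set and shape as the
# within-task-set stimulus; the shape expert does the reverse. Each expert
# clusters contexts into latent task-sets with a Chinese Restaurant Process
# prior, learns outcome probabilities p(r = 1 | S, a, Z) by beta counting,
# and acts through a noisy softmax. The agent's action is sampled from the
# reliability-weighted mixture of the two expert policies; the mixture
# weight w_C is updated by Bayes rule from how well each expert predicted
# the observed outcome. Motor biases (adjacency, left-right symmetry) can be
# routed into the policy only, or into both policy and outcome prediction.

# Finger neighborhood on 4 left-to-right positions.
.NEIGHBORS <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
.NEIGHBOR_KERNEL <- local({
  k <- matrix(0, 4L, 4L)
  for (i in 1:4) k[i, .NEIGHBORS[[i]]] <- 1 / length(.NEIGHBORS[[i]])
  k
})
# All 24 bijections (tsA.s1, tsA.s2, tsB.s1, tsB.s2) -> fingers, and which
# are left-right symmetric (same order of s1 vs s2 in both task-sets).
.SYM_PERMS <- local({
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  g <- g[apply(g, 1L, function(r) length(unique(r)) == 4L), , drop = FALSE]
  dimnames(g) <- NULL
  g
})
.SYM_OK <- (.SYM_PERMS[, 1L] < .SYM_PERMS[, 2L]) ==
  (.SYM_PERMS[, 3L] < .SYM_PERMS[, 4L])

#' Agent parameter set
#'
#' @param beta Softmax inverse temperature (> 0); default 30.
#' @param alpha Chinese Restaurant Process concentration (> 0); default 2.
#' @param epsilon Within-task-set lapse: a uniform choice mixed into the
#'   softmax policy with weight `epsilon`; default 0.1.
#' @param f Bias mixture weight: biased predictions are
#'   `(1 - f) * p_beta + f * bias`; default 0.1.
#' @param bias_adjacency,bias_symmetry Enable the motor adjacency bias and/or
#'   the left-right symmetry bias. When both are on they are mixed evenly.
#' @param routing Where biases act: `"prediction_and_policy"` (the full
#'   model: biased expected outcomes drive both choice and the outcome
#'   predictions used for inference), `"policy_only"` (biases tilt choice but
#'   predictions stay unbiased), or `"none"`.
#' @param bias_scope Apply biases on every trial (`"always"`, default) or
#'   only for stimulus cells without any observed outcome (`"unseen_only"`).
#' @param credit_spread If `TRUE`, reinforcement of an action also deposits
#'   fractional beta counts on neighboring actions for the task-set's other
#'   stimuli (an alternative mechanism to prediction bias).
#' @param credit_weight Total pseudo-count spread to neighbors per outcome;
#'   defaults to `f`.
#' @param map_likelihood If `TRUE` the mixture-weight update uses the MAP
#'   task-set's outcome likelihood; default (`FALSE`) marginalizes over the
#'   expert's task-set posterior for the current context.
#' @return A `motorstruct_params` list.
#' @export
agent_params <- function(beta = 30, alpha = 2, epsilon = 0.1, f = 0.1,
                         bias_adjacency = TRUE, bias_symmetry = TRUE,
                         routing = c("prediction_and_policy", "policy_only", "none"),
                         bias_scope = c("always", "unseen_only"),
                         credit_spread = FALSE, credit_weight = f,
                         map_likelihood = FALSE) {
  routing <- match.arg(routing)
  bias_scope <- match.arg(bias_scope)
  stopifnot(beta > 0, alpha > 0, epsilon >= 0, epsilon <= 1, f >= 0, f <= 1,
            credit_weight >= 0)
  structure(list(beta = beta, alpha = alpha, epsilon = epsilon, f = f,
                 bias_adjacency = bias_adjacency, bias_symmetry = bias_symmetry,
                 routing = routing, bias_scope = bias_scope,
                 credit_spread = credit_spread, credit_weight = credit_weight,
                 map_likelihood = map_likelihood),
            class = "motorstruct_params")
}

#' Create one structure expert
#'
#' An expert commits to one context dimension, clusters its context features
#' into latent task-sets, and learns beta-count outcome probabilities per
#' (task-set, stimulus feature, action). State has reference semantics (an
#' environment): update functions modify it in place.
#'
#' @param dimension `"color"` or `"shape"`: the dimension this expert treats
#'   as context; the other dimension provides the within-task-set stimuli.
#' @param n_features Number of context features (2 in all the tasks studied;
#'   larger values exercise the Chinese Restaurant Process prior with more
#'   task-sets).
#' @return A `motorstruct_expert` environment.
#' @export
new_expert <- function(dimension = c("color", "shape"), n_features = 2L) {
  dimension <- match.arg(dimension)
  e <- new.env(parent = emptyenv())
  e$dimension <- dimension
  e$ctx_seen <- rep(FALSE, n_features)
  e$P <- matrix(0, n_features, n_features)  # P(Z | C): contexts x task-sets
  e$n_ts <- 0L
  # task-set x stimulus feature x action
  e$succ <- array(0, c(n_features, 2L, 4L))
  e$fail <- array(0, c(n_features, 2L, 4L))
  class(e) <- "motorstruct_expert"
  e
}

#' @export
print.motorstruct_expert <- function(x, ...) {
  cat("<structure expert> context dimension:", x$dimension,
      "| task-sets:", x$n_ts, "| contexts seen:", sum(x$ctx_seen), "\n")
  invisible(x)
}

feature_index <- function(feature) as.integer(substr(feature, 2L, 2L))

#' Chinese Restaurant Process prior for a novel context
#'
#' For a context this expert has never seen, the prior probability of linking
#' it to an existing task-set is proportional to that task-set's popularity
#' (its summed posterior probability across known contexts) and the
#' probability of creating a new task-set is proportional to the
#' concentration `alpha`:
#' `P(Z_new) = alpha / (alpha + sum_i pop_i)`,
#' `P(Z_i) = pop_i / (alpha + sum_i pop_i)`.
#'
#' @param expert A [new_expert()].
#' @param context A context feature (e.g. `"c1"` for a color expert) not yet
#'   seen by this expert.
#' @param params An [agent_params()] (supplies `alpha`).
#' @return Named numeric prior over existing task-sets (`"TS1"`, ...) and
#'   `"new"`, summing to 1.
#' @export
crp_prior <- function(expert, context, params = agent_params()) {
  ci <- feature_index(context)
  if (expert$ctx_seen[ci]) {
    stop("context '", context, "' already known to this expert", call. = FALSE)
  }
  pop <- if (expert$n_ts > 0L) {
    colSums(expert$P[expert$ctx_seen, seq_len(expert$n_ts), drop = FALSE])
  } else numeric(0)
  z <- params$alpha + sum(pop)
  stats::setNames(c(pop / z, params$alpha / z),
                  c(if (expert$n_ts > 0L) paste0("TS", seq_len(expert$n_ts)), "new"))
}

# Instantiate a novel context: CRP prior becomes its initial P(Z | C), with
# the "new" mass assigned to a freshly registered task-set.
observe_context <- function(expert, context, params) {
  ci <- feature_index(context)
  if (expert$ctx_seen[ci]) return(invisible(expert))
  prior <- crp_prior(expert, context, params)
  expert$n_ts <- expert$n_ts + 1L
  expert$P[ci, seq_len(expert$n_ts)] <- prior
  expert$ctx_seen[ci] <- TRUE
  invisible(expert)
}

#' Maximum a priori task-set for a context
#'
#' @inheritParams crp_prior
#' @return Integer task-set id; ties break toward the lowest id.
#' @export
infer_taskset <- function(expert, context) {
  ci <- feature_index(context)
  if (!expert$ctx_seen[ci]) stop("context '", context, "' not yet observed",
                                 call. = FALSE)
  which.max(expert$P[ci, ])  # which.max takes the first (lowest id) on ties
}

# Beta-count expected outcome p(r = 1 | S, a, Z), Beta(1, 1) prior.
q_raw <- function(expert, Z, si) {
  s <- expert$succ[Z, si, ]
  (s + 1) / (s + expert$fail[Z, si, ] + 2)
}

softmax_policy <- function(q, params) {
  w <- exp(params$beta * (q - max(q)))
  (1 - params$epsilon) * w / sum(w) + params$epsilon / 4
}

#' Expert choice policy
#'
#' A noisy softmax on the expert's expected outcome for each action:
#' `pi = (1 - epsilon) * softmax(beta * q) + epsilon / 4`. Depending on
#' `params$routing`, `q` is the raw beta-count prediction or the
#' bias-mixed prediction (see [biased_prediction()]).
#'
#' @inheritParams crp_prior
#' @param Z Task-set id.
#' @param stimulus Stimulus-dimension feature (e.g. `"s1"` for a color
#'   expert).
#' @param context Current context feature; needed to evaluate the symmetry
#'   bias (which looks up the other context's task-set). Optional when no
#'   bias is active.
#' @return Numeric action distribution of length 4.
#' @export
expert_policy <- function(expert, Z, stimulus, params = agent_params(),
                          context = NULL) {
  si <- feature_index(stimulus)
  q <- if (params$routing == "none") q_raw(expert, Z, si)
       else bias_mixed_q(expert, Z, si, params, context)
  softmax_policy(q, params)
}

#' Motor adjacency bias distribution
#'
#' Spreads the expert's policy for the task-set's other stimuli onto
#' neighboring fingers: `bias(a) = sum_i pi(a_i | others(S), Z) *
#' neighbor(a | a_i)`, where `neighbor(a | a_i)` is `1 / #neighbors(a_i)`
#' for adjacent positions and 0 otherwise. The policy over the other
#' stimulus is the plain (unbiased) noisy softmax.
#'
#' @inheritParams expert_policy
#' @return Numeric action distribution of length 4.
#' @export
adjacency_bias <- function(expert, Z, stimulus, params = agent_params()) {
  si <- feature_index(stimulus)
  oi <- 3L - si
  pi_other <- softmax_policy(q_raw(expert, Z, oi), params)
  as.vector(pi_other %*% .NEIGHBOR_KERNEL)
}

#' Left-right symmetry bias distribution
#'
#' Distributes mass over finger positions in proportion to how many fully
#' left-right-symmetric assignment completions (same s1-vs-s2 finger order in
#' both task-sets) are consistent with what the expert currently knows and
#' would place the current stimulus there. "Known" cells are those
#' (task-set, stimulus) pairs with at least one recorded success; the other
#' task-set is the MAP task-set of the expert's other context. Uniform when
#' nothing constrains the completion.
#'
#' @inheritParams expert_policy
#' @param context The current context feature (required: the bias consults
#'   the other context's task-set).
#' @return Numeric action distribution of length 4.
#' @export
symmetry_bias <- function(expert, Z, stimulus, context, params = agent_params()) {
  unif <- rep(0.25, 4L)
  ci <- feature_index(context)
  oi_ctx <- 3L - ci
  if (!expert$ctx_seen[oi_ctx]) return(unif)
  Z2 <- which.max(expert$P[oi_ctx, ])
  if (Z2 == Z) return(unif)
  si <- feature_index(stimulus)
  # known finger per cell, order (Z,s1), (Z,s2), (Z2,s1), (Z2,s2)
  known <- rep(NA_integer_, 4L)
  cells <- rbind(c(Z, 1L), c(Z, 2L), c(Z2, 1L), c(Z2, 2L))
  for (k in 1:4) {
    sc <- expert$succ[cells[k, 1L], cells[k, 2L], ]
    if (any(sc > 0)) known[k] <- which.max(sc)
  }
  keep <- .SYM_OK
  for (k in which(!is.na(known))) keep <- keep & (.SYM_PERMS[, k] == known[k])
  if (!any(keep)) return(unif)
  counts <- tabulate(.SYM_PERMS[keep, si], 4L)
  if (sum(counts) == 0) return(unif)
  counts / sum(counts)
}

# Bias-mixed expected outcome vector used by the policy and (under
# prediction routing) by outcome prediction.
bias_mixed_q <- function(expert, Z, si, params, context = NULL) {
  q <- q_raw(expert, Z, si)
  if (!params$bias_adjacency && !params$bias_symmetry) return(q)
  if (params$bias_scope == "unseen_only" &&
      any(expert$succ[Z, si, ] + expert$fail[Z, si, ] > 0)) {
    return(q)
  }
  stimulus <- paste0("s", si)  # feature index is all the bias functions use
  bias <- 0
  nb <- 0L
  if (params$bias_adjacency) {
    bias <- bias + adjacency_bias(expert, Z, stimulus, params)
    nb <- nb + 1L
  }
  if (params$bias_symmetry) {
    if (is.null(context)) {
      ci <- if (expert$ctx_seen[1L]) 1L else 2L
      context <- paste0("x", ci)
    }
    bias <- bias + symmetry_bias(expert, Z, stimulus, context, params)
    nb <- nb + 1L
  }
  (1 - params$f) * q + params$f * bias / nb
}

#' Bias-mixed outcome prediction
#'
#' Under `routing = "prediction_and_policy"` the expert's expected outcome
#' for each action is `(1 - f) * p_beta + f * bias`, where `bias` is the
#' even mixture of the enabled bias distributions ([adjacency_bias()],
#' [symmetry_bias()]). Under any other routing the prediction is the raw
#' beta-count expectation (the operation is the identity on predictions).
#'
#' @inheritParams expert_policy
#' @param action Optional action index 1--4; if given, the scalar prediction
#'   for that action is returned instead of the length-4 vector.
#' @export
biased_prediction <- function(expert, Z, stimulus, params = agent_params(),
                              context = NULL, action = NULL) {
  si <- feature_index(stimulus)
  p <- if (params$routing == "prediction_and_policy") {
    bias_mixed_q(expert, Z, si, params, context)
  } else {
    q_raw(expert, Z, si)
  }
  if (is.null(action)) p else p[[action]]
}

#' Create an agent: two experts plus a mixture weight
#'
#' @param params An [agent_params()].
#' @return A `motorstruct_agent` environment with fields `color`, `shape`
#'   (the two experts), `w` (the color-structure mixture weight, initialized
#'   at 0.5) and `params`.
#' @export
new_agent <- function(params = agent_params()) {
  a <- new.env(parent = emptyenv())
  a$color <- new_expert("color")
  a$shape <- new_expert("shape")
  a$w <- 0.5
  a$params <- params
  class(a) <- "motorstruct_agent"
  a
}

#' @export
print.motorstruct_agent <- function(x, ...) {
  cat(sprintf("<structure-learning agent> w_C = %.3f, routing = %s\n",
              x$w, x$params$routing))
  invisible(x)
}

#' Choose an action for a stimulus
#'
#' Both experts compute their noisy-softmax policy for their MAP task-set
#' (observing the trial's context feature first if it is novel); the agent
#' samples from the reliability-weighted mixture
#' `pi = w_C * pi_color + (1 - w_C) * pi_shape`.
#'
#' @param agent A [new_agent()].
#' @param color,shape The trial's features (`"c1"`/`"c2"`, `"s1"`/`"s2"`).
#' @return List with `action` (1--4), `pi` (mixture), `pi_color`, `pi_shape`,
#'   `Z_color`, `Z_shape`.
#' @export
choose_action <- function(agent, color, shape) {
  p <- agent$params
  observe_context(agent$color, color, p)
  observe_context(agent$shape, shape, p)
  zc <- infer_taskset(agent$color, color)
  zs <- infer_taskset(agent$shape, shape)
  pic <- expert_policy(agent$color, zc, shape, p, context = color)
  pis <- expert_policy(agent$shape, zs, color, p, context = shape)
  pi <- agent$w * pic + (1 - agent$w) * pis
  act <- sample.int(4L, 1L, prob = pi)
  list(action = act, pi = pi, pi_color = pic, pi_shape = pis,
       Z_color = zc, Z_shape = zs)
}

#' Update one expert after an observed outcome
#'
#' Applies the Bayes update `P(Z | C) <- P(Z | C) * p(r | S, a, Z)`
#' (renormalized over the context's candidate task-sets), increments the
#' beta counts of the trial's MAP task-set for the chosen action, and, with
#' `credit_spread`, deposits fractional counts on neighboring actions for
#' the task-set's other stimulus. Predictions `p(r | S, a, Z)` are bias-mixed
#' under prediction routing (see [biased_prediction()]).
#'
#' @inheritParams crp_prior
#' @param stimulus Stimulus-dimension feature of the trial.
#' @param action Chosen action 1--4.
#' @param reward Outcome 0/1.
#' @param Z_map The MAP task-set inferred before the outcome (defaults to
#'   the current MAP).
#' @return The expert, invisibly (modified in place). The structure-level
#'   outcome likelihood used for the mixture update is stored in
#'   `expert$last_likelihood`.
#' @export
update_expert <- function(expert, context, stimulus, action, reward,
                          params = agent_params(), Z_map = NULL) {
  ci <- feature_index(context)
  si <- feature_index(stimulus)
  if (!expert$ctx_seen[ci]) observe_context(expert, context, params)
  if (is.null(Z_map)) Z_map <- which.max(expert$P[ci, ])
  cand <- which(expert$P[ci, ] > 0)
  lik <- vapply(cand, function(z) {
    pr <- biased_prediction(expert, z, stimulus, params, context = context,
                            action = action)
    if (reward == 1) pr else 1 - pr
  }, numeric(1))
  prior <- expert$P[ci, cand]
  expert$last_likelihood <- if (params$map_likelihood) {
    lik[[match(Z_map, cand)]]
  } else {
    sum(prior * lik)
  }
  post <- prior * lik
  expert$P[ci, cand] <- post / sum(post)
  expert$succ[Z_map, si, action] <- expert$succ[Z_map, si, action] + reward
  expert$fail[Z_map, si, action] <- expert$fail[Z_map, si, action] + (1 - reward)
  if (params$credit_spread && params$credit_weight > 0) {
    nb <- .NEIGHBORS[[action]]
    g <- params$credit_weight / length(nb)
    oi <- 3L - si
    expert$succ[Z_map, oi, nb] <- expert$succ[Z_map, oi, nb] + g * reward
    expert$fail[Z_map, oi, nb] <- expert$fail[Z_map, oi, nb] + g * (1 - reward)
  }
  invisible(expert)
}

#' Update the expert-mixture weight
#'
#' Bayes update of the color expert's reliability from the two experts'
#' outcome likelihoods: `w <- w * p_C / (w * p_C + (1 - w) * p_S)`.
#' Likelihoods are floored at 1e-6 to avoid absorbing states.
#'
#' @param agent A [new_agent()].
#' @param p_color,p_shape Each expert's probability of the realized outcome
#'   (defaults to the experts' stored `last_likelihood`).
#' @return The agent, invisibly (modified in place).
#' @export
update_mixture <- function(agent, p_color = agent$color$last_likelihood,
                           p_shape = agent$shape$last_likelihood) {
  pc <- max(p_color, 1e-6)
  ps <- max(p_shape, 1e-6)
  agent$w <- agent$w * pc / (agent$w * pc + (1 - agent$w) * ps)
  invisible(agent)
}

#' Simulate one learning block
#'
#' Runs the agent through a stimulus sequence against a ground-truth
#' contingency assignment (feedback is 1 iff the chosen finger matches the
#' assignment), returning per-trial records and the trajectory of the
#' mixture weight.
#'
#' @param params An [agent_params()].
#' @param assignment A [contingency_assignment()] (or a [structure_view()],
#'   whose assignment is used; feedback does not depend on the context role).
#' @param sequence A tibble from [generate_trial_sequence()] (columns
#'   `color`, `shape`).
#' @param seed Optional integer seed; the run is deterministic given the seed.
#' @return A `motorstruct_block_run`: list with `trials` (tibble: `trial`,
#'   `color`, `shape`, `action`, `correct`, `w_C`), `w_trajectory`,
#'   `final_w_C`, `params`, and `agent` (the final agent state).
#' @export
run_block <- function(params, assignment, sequence, seed = NULL) {
  if (inherits(assignment, "motorstruct_view")) assignment <- assignment$assignment
  if (!inherits(assignment, "motorstruct_assignment")) {
    assignment <- contingency_assignment(assignment)
  }
  stim <- paste0(sequence$color, ".", sequence$shape)
  bad <- setdiff(unique(stim), names(assignment))
  if (length(bad)) {
    stop("sequence contains stimuli absent from the assignment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  correct_act <- as.integer(assignment[stim])
  n <- length(stim)
  with_preserved_rng(seed, {
    agent <- new_agent(params)
    acts <- integer(n); rew <- integer(n); wtraj <- numeric(n)
    for (t in seq_len(n)) {
      ch <- choose_action(agent, sequence$color[[t]], sequence$shape[[t]])
      r <- as.integer(ch$action == correct_act[[t]])
      update_expert(agent$color, sequence$color[[t]], sequence$shape[[t]],
                    ch$action, r, params, Z_map = ch$Z_color)
      update_expert(agent$shape, sequence$shape[[t]], sequence$color[[t]],
                    ch$action, r, params, Z_map = ch$Z_shape)
      update_mixture(agent)
      acts[[t]] <- ch$action; rew[[t]] <- r; wtraj[[t]] <- agent$w
    }
    structure(
      list(trials = tibble::tibble(trial = seq_len(n), color = sequence$color,
                                   shape = sequence$shape, action = acts,
                                   correct = rew, w_C = wtraj),
           w_trajectory = wtraj, final_w_C = wtraj[[n]], params = params,
           agent = agent),
      class = "motorstruct_block_run"
    )
  })
}

#' @export
print.motorstruct_block_run <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<block run> %d trials, accuracy %.2f, final w_C = %.3f\n",
              n, mean(x$trials$correct), x$final_w_C))
  invisible(x)
}
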