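# Synthetic-behavior generator: trial-level cohorts with the statistical
# structure the switch-cost analysis assumes (learning curves, log-normal
# RTs, an additive context-switch cost on the created structure's dimension,
# sequential finger-repetition effects), plus ground-truth labels for
# recovery scoring.

#' Generator settings for synthetic behavior
#'
#' Defaults emulate the learning experiments' effect structure: a population
#' bias of 2/3 toward creating the higher-adjacency structure, a 600 ms
#' log-normal RT base (sdlog 0.2, i.e. ~120 ms spread), an 80 ms
#' context-switch cost on the created structure's dimension, a 30 ms
#' stimulus-switch cost, and a 20 ms speed-up on finger repetitions. The
#' default block length (400 trials) is a power choice for pipeline
#' validation, not an emulation of any experiment's block length: it leaves
#' roughly 120 correct, transition-labeled trials per block after
#' asymptotic filtering, enough for the per-block switch-cost contrast
#' (signal 50 ms, the context minus stimulus switch cost) to be comfortably
#' identifiable. Set `n_trials = 80` for learning-experiment-scale blocks.
#'
#' @param n_trials Trials per block (>= 16, divisible by 4).
#' @param q Probability that a block's created structure is the
#'   higher-adjacency view.
#' @param delta_context Context-switch RT cost in ms on the created view's
#'   context dimension.
#' @param delta_stimulus Stimulus-dimension switch RT cost in ms.
#' @param rt_base Median baseline RT in ms.
#' @param rt_sdlog Log-normal sd of the RT base.
#' @param repeat_speedup Finger-repetition speed-up in ms.
#' @param rt_floor Minimum RT in ms (truncation).
#' @param learn_rate,learn_midpoint Logistic learning curve for accuracy:
#'   `p(correct at t) = 0.25 + (asymptote - 0.25) * plogis(learn_rate *
#'   (t - learn_midpoint))`.
#' @param asymptote Asymptotic accuracy of the learning curve.
#' @param choice_source `"learning_curve"` (parametric accuracy) or
#'   `"agent"` (choices simulated from [run_block()] with `agent_params`).
#' @param agent_params Used when `choice_source = "agent"`.
#' @param no_repeats Generate sequences without immediate stimulus repeats
#'   (instructed-style blocks).
#' @return A `motorstruct_generator_spec` list.
#' @export
generator_spec <- function(n_trials = 400, q = 2 / 3, delta_context = 80,
                           delta_stimulus = 30, rt_base = 600, rt_sdlog = 0.2,
                           repeat_speedup = 20, rt_floor = 150,
                           learn_rate = 0.2, learn_midpoint = 10,
                           asymptote = 0.95,
                           choice_source = c("learning_curve", "agent"),
                           agent_params = NULL, no_repeats = FALSE) {
  stopifnot(q >= 0, q <= 1, delta_context >= 0, delta_stimulus >= 0,
            rt_base > 0, repeat_speedup >= 0, asymptote > 0.25, asymptote <= 1)
  structure(list(n_trials = n_trials, q = q, delta_context = delta_context,
                 delta_stimulus = delta_stimulus, rt_base = rt_base,
                 rt_sdlog = rt_sdlog, repeat_speedup = repeat_speedup,
                 rt_floor = rt_floor, learn_rate = learn_rate,
                 learn_midpoint = learn_midpoint, asymptote = asymptote,
                 choice_source = match.arg(choice_source),
                 agent_params = agent_params, no_repeats = no_repeats),
            class = "motorstruct_generator_spec")
}

#' Generate one synthetic block of trials
#'
#' Stimuli come from [generate_trial_sequence()]; choices either follow a
#' logistic learning curve (errors pick uniformly among the three wrong
#' fingers) or are simulated by the structure-learning agent. RT is
#' `exp(N(log(rt_base), rt_sdlog))` plus `delta_context` on trials where the
#' created view's context feature switches, plus `delta_stimulus` on
#' stimulus-dimension switches, minus `repeat_speedup` on finger
#' repetitions, truncated at `rt_floor`.
#'
#' @param spec A [generator_spec()].
#' @param assignment A [contingency_assignment()].
#' @param created `"color"` or `"shape"`: the context dimension of the
#'   structure the simulated subject created.
#' @param seed Optional integer seed.
#' @param block,subject Identifiers attached to the records.
#' @return Tibble of trial records (`subject`, `block`, `trial`, `color`,
#'   `shape`, `finger`, `correct`, `rt`).
#' @export
generate_block <- function(spec, assignment, created = c("color", "shape"),
                           seed = NULL, block = 1L, subject = 1L) {
  created <- match.arg(created)
  if (!inherits(assignment, "motorstruct_assignment")) {
    assignment <- contingency_assignment(assignment)
  }
  with_preserved_rng(seed, {
    sq <- generate_trial_sequence(spec$n_trials, no_repeats = spec$no_repeats)
    n <- spec$n_trials
    correct_act <- as.integer(assignment[sq$stimulus])
    if (spec$choice_source == "agent") {
      ap <- spec$agent_params
      if (is.null(ap)) ap <- agent_params()
      blk <- run_block(ap, assignment, sq)
      finger <- blk$trials$action
    } else {
      p_t <- 0.25 + (spec$asymptote - 0.25) *
        stats::plogis(spec$learn_rate * (seq_len(n) - spec$learn_midpoint))
      hit <- stats::runif(n) < p_t
      # errors are uniform over the three wrong fingers: rotate by 1..3
      offset <- sample.int(3L, n, replace = TRUE)
      finger <- ifelse(hit, correct_act, (correct_act - 1L + offset) %% 4L + 1L)
    }
    correct <- as.integer(finger == correct_act)
    ctx_feat <- if (created == "color") sq$color else sq$shape
    stim_feat <- if (created == "color") sq$shape else sq$color
    ctx_switch <- c(FALSE, ctx_feat[-1L] != ctx_feat[-n])
    stim_switch <- c(FALSE, stim_feat[-1L] != stim_feat[-n])
    fing_repeat <- c(FALSE, finger[-1L] == finger[-n])
    rt <- exp(stats::rnorm(n, log(spec$rt_base), spec$rt_sdlog)) +
      spec$delta_context * ctx_switch +
      spec$delta_stimulus * stim_switch -
      spec$repeat_speedup * fing_repeat
    rt <- pmax(rt, spec$rt_floor)
    tibble::tibble(subject = subject, block = block, trial = seq_len(n),
                   color = sq$color, shape = sq$shape, finger = finger,
                   correct = correct, rt = rt)
  })
}

#' Generate a synthetic cohort with ground-truth structure labels
#'
#' Draws, for each block, a configuration (P1/P2 or P3/P4 sibling pair), a
#' counterbalanced representative assignment, and a created structure: the
#' higher-adjacency view with probability `spec$q`, the lower-adjacency view
#' otherwise. In instructed mode an instructed view is also assigned
#' (balanced across blocks) and the created view is drawn independently of
#' it, reproducing the restructuring scenario. Trial records for all blocks
#' are generated with [generate_block()].
#'
#' @param spec A [generator_spec()].
#' @param n_blocks Total number of blocks.
#' @param n_subjects Number of subjects; blocks are dealt round-robin.
#' @param config_mix Named proportions of the two analyzed sibling-pair
#'   configurations.
#' @param instructed If `TRUE`, attach balanced instructed views.
#' @param seed Optional integer seed.
#' @return A `motorstruct_cohort`: list with `trials` (all trial records)
#'   and `metadata` (per block: `block`, `subject`, `config`, `assignment`
#'   list-column, `high_dimension`, `created`, `created_is_high`, and
#'   `instructed` when applicable).
#' @export
generate_cohort <- function(spec = generator_spec(), n_blocks = 99,
                            n_subjects = 22,
                            config_mix = c("P1/P2" = 40 / 99, "P3/P4" = 59 / 99),
                            instructed = FALSE, seed = NULL) {
  stopifnot(n_blocks >= 1, abs(sum(config_mix) - 1) < 1e-8)
  with_preserved_rng(seed, {
    # counterbalance color/shape roles: half the representatives put the
    # higher-adjacency view on color, half on shape
    reps <- list("P1/P2" = c(class_representatives("P1"),
                             class_representatives("P2")),
                 "P3/P4" = c(class_representatives("P3"),
                             class_representatives("P4")))
    n_cfg <- round(n_blocks * config_mix)
    n_cfg[[1L]] <- n_blocks - sum(n_cfg[-1L])
    configs <- sample(rep(names(config_mix), n_cfg))
    meta <- vector("list", n_blocks)
    trials <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      cfg <- configs[[b]]
      view <- reps[[cfg]][[(b - 1L) %% length(reps[[cfg]]) + 1L]]
      asg <- view$assignment
      cls <- classify_pattern(view)$class
      high <- if (cls %in% c("P1", "P3")) "color" else "shape"
      created <- if (stats::runif(1) < spec$q) high else other_dimension(high)
      subject <- (b - 1L) %% n_subjects + 1L
      row <- tibble::tibble(block = b, subject = subject, config = cfg,
                            assignment = list(asg), high_dimension = high,
                            created = created,
                            created_is_high = created == high)
      if (instructed) {
        row$instructed <- if (b %% 2L == 0L) "color" else "shape"
      }
      meta[[b]] <- row
      trials[[b]] <- generate_block(spec, asg, created, block = b,
                                    subject = subject)
    }
    structure(list(trials = dplyr::bind_rows(trials),
                   metadata = dplyr::bind_rows(meta), spec = spec),
              class = "motorstruct_cohort")
  })
}

#' @export
print.motorstruct_cohort <- function(x, ...) {
  cat("<synthetic cohort>", nrow(x$metadata), "blocks,",
      length(unique(x$metadata$subject)), "subjects,",
      nrow(x$trials), "trials\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Trial records go to `trials.csv`; ground-truth metadata to
#' `metadata.json` (assignments serialized as stimulus-finger maps).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$trials, file.path(dir, "trials.csv"))
  meta <- cohort$metadata
  meta$assignment <- vapply(meta$assignment, function(a) {
    as.character(view_to_json(structure_view(a, "color")))
  }, "")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a trial-record CSV
#'
#' Expects the documented column set (`subject`, `block`, `trial`, `color`,
#' `shape`, `finger`, `correct`, `rt`).
#'
#' @param path CSV path.
#' @return Tibble of trial records.
#' @export
read_trials_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("subject", "block", "trial", "color", "shape", "finger",
              "correct", "rt")
  miss <- setdiff(needed, names(tr))
  if (length(miss)) stop("trial CSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tr
}
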