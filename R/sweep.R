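# Simulation experiments: configuration sweeps over pattern classes and bias
# routings, producing the structure-preference table (mean final mixture
# weight per class) and the policy-only null contrast.

#' Run a configuration sweep of block simulations
#'
#' For each (pattern class, bias routing) cell, simulates `n_runs` learning
#' blocks of `n_trials` trials and collects the color-structure expert's
#' final mixture weight `w_C`. The class labels the *color-as-context* view
#' of the assignment used, so for P1/P3 cells the color structure is the
#' higher-adjacency view and `w_C > 0.5` means the model prefers it.
#' Representative assignments are counterbalanced by cycling the class's
#' color-context members of the relabeling orbit across runs; every run uses
#' a freshly generated balanced stimulus sequence. Deterministic given
#' `base_seed`.
#'
#' @param classes Pattern classes to sweep; default `P1`--`P4` (the
#'   `{2,1}`-pair classes P5/P6 carry an independent symmetry confound and
#'   are not swept by default).
#' @param routings Bias routings to contrast (see [agent_params()]).
#' @param n_runs Simulated blocks per cell; default 1000.
#' @param n_trials Trials per block; default 80.
#' @param base_seed Integer seed for the whole sweep.
#' @param params Base [agent_params()]; its `routing` field is overridden
#'   per cell.
#' @return A `motorstruct_sweep`: list with `runs` (tibble: `class`,
#'   `routing`, `run`, `final_w_C`, `accuracy`) and `summary` (tibble:
#'   `class`, `routing`, `mean_w`, `se_w`, `n`).
#' @export
run_sweep <- function(classes = c("P1", "P2", "P3", "P4"),
                      routings = c("prediction_and_policy", "policy_only"),
                      n_runs = 1000, n_trials = 80, base_seed = 1,
                      params = agent_params()) {
  stopifnot(n_runs >= 1, all(classes %in% paste0("P", 1:6)))
  cells <- expand.grid(class = classes, routing = routings,
                       stringsAsFactors = FALSE)
  runs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells$class[[i]]
    p <- params
    p$routing <- cells$routing[[i]]
    reps <- class_representatives(cl)
    seeds <- derive_seeds(base_seed, n_runs, stream = i)
    w <- numeric(n_runs); acc <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      view <- reps[[(r - 1L) %% length(reps) + 1L]]
      sq <- generate_trial_sequence(n_trials, seed = seeds[[r]])
      blk <- run_block(p, view, sq, seed = seeds[[r]] + 1)
      w[[r]] <- blk$final_w_C
      acc[[r]] <- mean(blk$trials$correct)
    }
    runs[[i]] <- tibble::tibble(class = cl, routing = cells$routing[[i]],
                                run = seq_len(n_runs), final_w_C = w,
                                accuracy = acc)
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$class, .data$routing) |>
    dplyr::summarise(mean_w = mean(.data$final_w_C),
                     se_w = stats::sd(.data$final_w_C) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  structure(list(runs = runs, summary = summary,
                 spec = list(classes = classes, routings = routings,
                             n_runs = n_runs, n_trials = n_trials,
                             base_seed = base_seed)),
            class = "motorstruct_sweep")
}

#' @export
print.motorstruct_sweep <- function(x, ...) {
  cat("<simulation sweep>", x$spec$n_runs, "runs x", x$spec$n_trials,
      "trials per cell\n")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Structure-preference table from a sweep
#'
#' For each cell, the fraction of runs whose final mixture weight favors the
#' higher-adjacency view of the assignment (for P1/P3 the color structure,
#' `w_C > 0.5`; for P2/P4 the shape structure, `w_C < 0.5`). Exact ties at
#' 0.5 are broken by a fair coin so a perfectly indifferent model scores
#' 0.5 in expectation.
#'
#' @param sweep A [run_sweep()] result.
#' @param seed Optional seed for the tie-breaking coin.
#' @return Tibble: `class`, `routing`, `n`, `frac_high_adjacency`,
#'   `ci_lo`, `ci_hi` (exact binomial 95% CI).
#' @export
summarize_preferences <- function(sweep, seed = NULL) {
  stopifnot(inherits(sweep, "motorstruct_sweep"))
  with_preserved_rng(seed, {
    runs <- sweep$runs
    high_is_color <- runs$class %in% c("P1", "P3", "P5")
    tie <- runs$final_w_C == 0.5
    coin <- stats::runif(nrow(runs)) < 0.5
    fav_color <- ifelse(tie, coin, runs$final_w_C > 0.5)
    runs$favors_high <- ifelse(high_is_color, fav_color, !fav_color)
    runs |>
      dplyr::group_by(.data$class, .data$routing) |>
      dplyr::summarise(n = dplyr::n(), k = sum(.data$favors_high),
                       .groups = "drop") |>
      dplyr::mutate(
        frac_high_adjacency = .data$k / .data$n,
        ci = lapply(seq_along(.data$n), function(i) {
          stats::binom.test(.data$k[[i]], .data$n[[i]])$conf.int
        }),
        ci_lo = vapply(.data$ci, `[`, numeric(1), 1L),
        ci_hi = vapply(.data$ci, `[`, numeric(1), 2L)
      ) |>
      dplyr::select(!dplyr::all_of(c("k", "ci")))
  })
}

#' Write sweep outputs
#'
#' Writes the per-run table and the summary as CSV next to a JSON echo of
#' the sweep spec.
#'
#' @param sweep A [run_sweep()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sweep$runs, file.path(dir, "sweep_runs.csv"))
  readr::write_csv(sweep$summary, file.path(dir, "sweep_summary.csv"))
  jsonlite::write_json(sweep$spec, file.path(dir, "sweep_spec.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Plot mean final mixture weight per pattern class
#'
#' A point-and-errorbar figure of the sweep summary (mean `w_C` with
#' standard error, by class and routing). Requires ggplot2.
#'
#' @param sweep A [run_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep() needs the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(sweep$summary,
                  ggplot2::aes(x = .data$class, y = .data$mean_w,
                               color = .data$routing, group = .data$routing)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_w - .data$se_w,
                                          ymax = .data$mean_w + .data$se_w)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "color-structure pattern class",
                  y = "mean final w_C") +
    ggplot2::theme_minimal()
}
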