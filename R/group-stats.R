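# Group-level statistics: exact binomial and one-sample t tests, and the
# two-level cohort report (block -> subject-by-configuration average ->
# group test; block labels -> binomial count).

#' Exact two-sided binomial test
#'
#' Exact two-sided p-value for `k` successes out of `n` under success
#' probability `p0`, summing the probabilities of all outcomes no more
#' likely than the observed one (the standard small-p-value definition,
#' as in [stats::binom.test()]).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return Two-sided p-value.
#' @examples
#' exact_binomial_test(66, 99) # ~0.0012
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= 1, k <= n,
            p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0)$p.value
}

#' One-sample t test
#'
#' @param values Numeric sample.
#' @param mu0 Null mean.
#' @return List with `t`, `df`, `p`, `mean`, `se`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance sample", call. = FALSE)
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values),
       se = stats::sd(values) / sqrt(length(values)))
}

#' Full cohort analysis report
#'
#' Runs the complete structure-identification pipeline on a cohort of
#' trial-level records: per block, transitions are labeled, the asymptotic
#' window is selected, per-dimension switch costs are estimated and the
#' motor-clustering contrast computed ([motor_clustering_switch_cost()]).
#' Block results are then averaged within subject and configuration type
#' before the group one-sample t test on the motor-clustering switch cost,
#' and block-level structure labels are counted against a fair coin with an
#' exact binomial test. When `metadata` carries an `instructed` column the
#' instructed switch cost is reported per block and tested at the group
#' level too.
#'
#' @param trials Trial records (`subject`, `block`, `trial`, `color`,
#'   `shape`, `finger`, `correct`, `rt`).
#' @param metadata One row per block: `block`, `subject`, `assignment`
#'   (list-column of [contingency_assignment()]s or JSON strings from
#'   [view_to_json()]), optionally `instructed` (`"color"`/`"shape"`).
#' @param policy An [asymptote_policy()].
#' @param min_per_cell Passed to [dimension_switch_cost()].
#' @return A `motorstruct_cohort_report`: list with `blocks` (tibble of
#'   per-block switch costs and labels), `group` (list: `mean_mcsc`,
#'   `t_test`, `n_high`, `n_labeled`, `binomial_p`, and instructed analogues
#'   when applicable).
#' @export
cohort_report <- function(trials, metadata, policy = asymptote_policy(),
                          min_per_cell = 5L) {
  missing_meta <- setdiff(unique(trials$block), metadata$block)
  if (length(missing_meta)) {
    stop("no metadata for block(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  labeled <- label_transitions(trials)
  filtered <- asymptotic_filter(labeled, policy)
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    b <- metadata$block[[i]]
    asg <- metadata$assignment[[i]]
    if (is.character(asg)) asg <- view_from_json(asg)$assignment
    bt <- filtered[filtered$block == b, ]
    mc <- motor_clustering_switch_cost(bt, asg, min_per_cell)
    cls <- classify_pattern(structure_view(asg, "color"))
    out <- tibble::tibble(
      block = b, subject = metadata$subject[[i]],
      config = paste(sort(c(cls$class, sibling_class(cls$class)),
                          decreasing = FALSE), collapse = "/"),
      n_usable = nrow(bt),
      swc_color = mc$swc_color, swc_shape = mc$swc_shape,
      high_dimension = mc$high_dimension,
      motor_clustering_swc = mc$value, label = mc$label
    )
    if ("instructed" %in% names(metadata)) {
      out$instructed <- metadata$instructed[[i]]
      out$instructed_swc <- instructed_switch_cost(bt, metadata$instructed[[i]],
                                                   min_per_cell)
    }
    out
  })
  blocks <- dplyr::bind_rows(rows)

  subj <- blocks |>
    dplyr::filter(!is.na(.data$motor_clustering_swc)) |>
    dplyr::group_by(.data$subject, .data$config) |>
    dplyr::summarise(mcsc = mean(.data$motor_clustering_swc), .groups = "drop")
  group <- list(
    mean_mcsc = mean(subj$mcsc),
    t_test = if (nrow(subj) >= 2L && stats::sd(subj$mcsc) > 0) {
      one_sample_t(subj$mcsc)
    },
    n_high = sum(blocks$label == "high-adjacency"),
    n_labeled = sum(blocks$label != "indeterminate")
  )
  group$binomial_p <- if (group$n_labeled > 0L) {
    exact_binomial_test(group$n_high, group$n_labeled, 0.5)
  } else NA_real_
  if ("instructed_swc" %in% names(blocks)) {
    isubj <- blocks |>
      dplyr::filter(!is.na(.data$instructed_swc)) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(iswc = mean(.data$instructed_swc), .groups = "drop")
    group$mean_instructed_swc <- mean(isubj$iswc)
    group$instructed_t_test <- if (nrow(isubj) >= 2L && stats::sd(isubj$iswc) > 0) {
      one_sample_t(isubj$iswc)
    }
  }
  structure(list(blocks = blocks, group = group),
            class = "motorstruct_cohort_report")
}

sibling_class <- function(class) {
  c(P1 = "P2", P2 = "P1", P3 = "P4", P4 = "P3", P5 = "P6", P6 = "P5")[[class]]
}

#' @export
print.motorstruct_cohort_report <- function(x, ...) {
  g <- x$group
  cat("<cohort report>", nrow(x$blocks), "blocks,",
      g$n_labeled, "labeled\n")
  cat(sprintf("  mean motor-clustering switch cost: %.1f ms\n", g$mean_mcsc))
  if (!is.null(g$t_test)) {
    cat(sprintf("  group t(%d) = %.2f, p = %.4g\n",
                g$t_test$df, g$t_test$t, g$t_test$p))
  }
  cat(sprintf("  high-adjacency labels: %d / %d (binomial p = %.4g)\n",
              g$n_high, g$n_labeled, g$binomial_p))
  if (!is.null(g$mean_instructed_swc)) {
    cat(sprintf("  mean instructed switch cost: %.1f ms\n",
                g$mean_instructed_swc))
  }
  invisible(x)
}
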