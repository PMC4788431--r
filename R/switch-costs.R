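# Reaction-time switch-cost analysis: transition labelling, asymptotic
# filtering, per-dimension switch costs corrected for sequential motor
# effects, and the motor-clustering / instructed contrasts that identify
# which structure was created.

#' Label trial-to-trial transitions
#'
#' Adds transition flags by comparing each trial with the previous one within
#' its block: `color_switch`, `shape_switch`, `full_repeat` (both features
#' repeat), `prev_finger`, `finger_repeat`, and `finger_dist` (absolute
#' position difference of consecutive responses). First trials of a block
#' get `NA` flags.
#'
#' @param trials Tibble of trial records with at least `block`, `trial`,
#'   `color`, `shape`, `finger` (integer position 1--4); sorted or sortable
#'   by `trial` within `block`.
#' @return The trials with transition columns appended, sorted by block and
#'   trial.
#' @export
label_transitions <- function(trials) {
  needed <- c("block", "trial", "color", "shape", "finger")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dup <- trials |>
    dplyr::count(.data$block, .data$trial) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate trial indices within block(s): ",
         paste(unique(dup$block), collapse = ", "), call. = FALSE)
  }
  trials |>
    dplyr::arrange(.data$block, .data$trial) |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(
      color_switch = .data$color != dplyr::lag(.data$color),
      shape_switch = .data$shape != dplyr::lag(.data$shape),
      full_repeat = !.data$color_switch & !.data$shape_switch,
      prev_finger = dplyr::lag(.data$finger),
      finger_repeat = .data$finger == .data$prev_finger,
      finger_dist = abs(.data$finger - .data$prev_finger)
    ) |>
    dplyr::ungroup()
}

#' Asymptotic-performance filtering policy
#'
#' @param second_half Keep only trials in the second half of the block?
#' @param criterion_streak Performance criterion: trials are kept from the
#'   start of a run of at least this many consecutive correct trials.
#'   `NULL` disables the criterion.
#' @param criterion Which qualifying run marks the criterion: `"first"`
#'   (default; the classic learning-criterion reading, under which sporadic
#'   post-asymptotic errors do not shrink the window) or `"last"` (a
#'   stricter relapse-guarding variant).
#' @return A `motorstruct_asymptote_policy` list.
#' @export
asymptote_policy <- function(second_half = TRUE, criterion_streak = 8L,
                             criterion = c("first", "last")) {
  structure(list(second_half = second_half,
                 criterion_streak = criterion_streak,
                 criterion = match.arg(criterion)),
            class = "motorstruct_asymptote_policy")
}

#' Keep correct trials at asymptotic performance
#'
#' Retains correct trials inside the asymptotic window of each block:
#' by default, trials in the second half of the block that are at or after
#' the start of the block's first streak of >= 8 consecutive correct trials
#' (the learning criterion).
#' Blocks never reaching the criterion contribute no trials (with a
#' warning), which downstream yields an indeterminate structure label.
#'
#' @param trials Labeled trial records (see [label_transitions()]) with a
#'   `correct` column (0/1 or logical).
#' @param policy An [asymptote_policy()].
#' @return The retained subset of `trials`.
#' @export
asymptotic_filter <- function(trials, policy = asymptote_policy()) {
  out <- trials |>
    dplyr::group_by(.data$block) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$trial), ]
      from <- 1L
      if (policy$second_half) from <- max(from, floor(nrow(df) / 2) + 1L)
      if (!is.null(policy$criterion_streak)) {
        crit <- streak_start(as.integer(df$correct) == 1L,
                             policy$criterion_streak, policy$criterion)
        if (is.na(crit)) {
          warning("block ", key$block, " never reached the ",
                  policy$criterion_streak, "-trial correct criterion; ",
                  "no asymptotic trials retained", call. = FALSE)
          return(df[0L, ])
        }
        from <- max(from, crit)
      }
      df[seq_len(nrow(df)) >= from & as.integer(df$correct) == 1L, ]
    }) |>
    dplyr::ungroup()
  out
}

# Start index of the first (or last) maximal run of >= k consecutive TRUEs.
streak_start <- function(ok, k, which_run = "first") {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  i <- if (which_run == "first") hit[[1L]] else hit[[length(hit)]]
  ends[[i]] - r$lengths[[i]] + 1L
}

#' Reaction-time switch cost of one feature dimension
#'
#' Estimates the RT slowing on trials where the queried dimension's feature
#' changes versus repeats, controlling for sequential motor effects. An
#' additive model of log RT on both dimensions' switch flags, a
#' finger-repetition flag and the absolute finger distance is fit to the
#' (filtered, labeled) trials; the returned value is the back-transformed
#' effect in ms of the queried switch flag evaluated at the sample mean of
#' the covariates. When the design is collinear the raw mean RT difference
#' (switch minus repeat) is returned instead. Full-repeat trials and
#' unlabeled first trials are excluded.
#'
#' @param trials Labeled (and typically asymptotically filtered) trial
#'   records with an `rt` column in ms.
#' @param dimension `"color"` or `"shape"`.
#' @param min_per_cell Minimum switch and repeat trials required; below this
#'   the estimate is `NA` (indeterminate).
#' @return Switch cost in ms (possibly `NA`).
#' @export
dimension_switch_cost <- function(trials, dimension = c("color", "shape"),
                                  min_per_cell = 5L) {
  dimension <- match.arg(dimension)
  switch_cost_fit(trials, min_per_cell)[[dimension]]
}

# One additive log-RT fit per block, returning both dimensions' ms effects.
switch_cost_fit <- function(trials, min_per_cell = 5L) {
  keep <- !is.na(trials$color_switch) & !trials$full_repeat
  df <- trials[keep, c("rt", "color_switch", "shape_switch", "finger_repeat",
                       "finger_dist")]
  out <- c(color = NA_real_, shape = NA_real_)
  estimable <- c(
    color = sum(df$color_switch) >= min_per_cell &&
      sum(!df$color_switch) >= min_per_cell,
    shape = sum(df$shape_switch) >= min_per_cell &&
      sum(!df$shape_switch) >= min_per_cell
  )
  if (!any(estimable)) return(as.list(out))
  X <- cbind(1, df$color_switch, df$shape_switch, df$finger_repeat,
             df$finger_dist)
  colnames(X) <- c("(Intercept)", "color", "shape", "finger_repeat",
                   "finger_dist")
  # constant covariates (e.g. no finger repetitions survive filtering) carry
  # no information; drop them rather than flagging collinearity
  keep_col <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, stats::var) > 0)
  X <- X[, keep_col, drop = FALSE]
  fit <- stats::lm.fit(X, log(df$rt))
  co <- fit$coefficients
  xbar <- colMeans(X)
  for (d in c("color", "shape")) {
    if (!estimable[[d]]) next
    flag <- if (d == "color") df$color_switch else df$shape_switch
    if (!d %in% colnames(X) || is.na(co[[d]])) {
      # the flag is constant or collinear with other covariates: fall back
      # to the raw mean RT difference
      out[[d]] <- mean(df$rt[flag]) - mean(df$rt[!flag])
    } else {
      x0 <- xbar; x0[[d]] <- 0
      x1 <- xbar; x1[[d]] <- 1
      x0[is.na(co)] <- 0; x1[is.na(co)] <- 0
      co0 <- co; co0[is.na(co0)] <- 0
      out[[d]] <- unname(exp(sum(x1 * co0)) - exp(sum(x0 * co0)))
    }
  }
  as.list(out)
}

#' Motor-clustering switch cost and structure label for one block
#'
#' Identifies which of the block's two structure views has the higher
#' adjacency bonus and returns the switch cost of that view's context
#' dimension minus the other's. A positive value labels the block as
#' structured by the higher-adjacency view. Blocks whose views form the
#' \{2,1\} adjacency pair (classes P5/P6) are excluded, as their preference
#' is confounded by the symmetry bias.
#'
#' @param trials One block's labeled, filtered trial records.
#' @param assignment The block's [contingency_assignment()].
#' @param min_per_cell Passed to [dimension_switch_cost()].
#' @return List with `value` (ms), `label` (`"high-adjacency"`,
#'   `"low-adjacency"` or `"indeterminate"`), `swc_color`, `swc_shape`,
#'   `high_dimension`.
#' @export
motor_clustering_switch_cost <- function(trials, assignment, min_per_cell = 5L) {
  if (!inherits(assignment, "motorstruct_assignment")) {
    assignment <- contingency_assignment(assignment)
  }
  a_col <- adjacency_bonus(structure_view(assignment, "color"))
  a_shp <- adjacency_bonus(structure_view(assignment, "shape"))
  if (setequal(c(a_col, a_shp), c(2L, 1L))) {
    stop("assignment belongs to the P5/P6 sibling pair; ",
         "motor-clustering contrast is not defined for it", call. = FALSE)
  }
  high <- if (a_col > a_shp) "color" else "shape"
  fit <- switch_cost_fit(trials, min_per_cell)
  swc_c <- fit$color
  swc_s <- fit$shape
  value <- if (high == "color") swc_c - swc_s else swc_s - swc_c
  label <- if (is.na(value)) "indeterminate"
           else if (value > 0) "high-adjacency" else "low-adjacency"
  list(value = value, label = label, swc_color = swc_c, swc_shape = swc_s,
       high_dimension = high)
}

#' Instructed switch cost for one block
#'
#' Switch cost of the instructed structure's context dimension minus the
#' other dimension's. Negative values indicate the subject restructured the
#' task away from the instructed view.
#'
#' @param trials One block's labeled, filtered trial records.
#' @param instructed `"color"` or `"shape"`: the instructed context
#'   dimension.
#' @param min_per_cell Passed to [dimension_switch_cost()].
#' @return Instructed switch cost in ms (possibly `NA`).
#' @export
instructed_switch_cost <- function(trials, instructed = c("color", "shape"),
                                   min_per_cell = 5L) {
  instructed <- match.arg(instructed)
  fit <- switch_cost_fit(trials, min_per_cell)
  fit[[instructed]] - fit[[other_dimension(instructed)]]
}
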