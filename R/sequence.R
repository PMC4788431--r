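# Pseudo-randomized trial sequences with equal stimulus presentation and
# equal first-order transition frequencies.
#
# Construction: the sequence is an Eulerian path in a directed multigraph on
# the 4 stimuli whose edge multiplicities are as equal as possible (all
# within +-1) subject to the walk visiting every stimulus exactly n/4 times.
# A randomized Hierholzer traversal then yields a uniform-ish pseudo-random
# sequence satisfying the balance constraints exactly.

#' Generate a balanced pseudo-random stimulus sequence
#'
#' Produces a sequence of the four two-feature stimuli in which each stimulus
#' appears exactly `n_trials / 4` times and each permitted first-order
#' transition (ordered stimulus pair) occurs equally often, within one
#' occurrence. With `no_repeats = TRUE` immediate stimulus repetitions are
#' excluded (as in instructed task-switching blocks) and the 12 non-repeat
#' transitions are balanced; otherwise all 16 transitions are.
#'
#' @param n_trials Number of trials; must be at least 16 and divisible by 4.
#' @param no_repeats Exclude immediate repetitions of the same stimulus?
#' @param seed Optional integer seed; the sequence is deterministic given the
#'   seed and does not disturb the caller's RNG state.
#' @return A tibble with columns `trial`, `color`, `shape`, `stimulus`.
#' @examples
#' seq80 <- generate_trial_sequence(80, seed = 1)
#' table(seq80$stimulus)
#' @export
generate_trial_sequence <- function(n_trials, no_repeats = FALSE, seed = NULL) {
  if (n_trials < 16L || n_trials %% 4L != 0L) {
    stop("n_trials must be >= 16 and divisible by 4", call. = FALSE)
  }
  with_preserved_rng(seed, {
    for (attempt in 1:100) {
      idx <- try_balanced_walk(as.integer(n_trials), no_repeats)
      if (!is.null(idx)) break
    }
    if (is.null(idx)) {
      stop("could not satisfy transition balance for n_trials = ", n_trials,
           if (no_repeats) " with no_repeats" else "", call. = FALSE)
    }
    feats <- stimulus_features(.STIMULI[idx])
    tibble::tibble(trial = seq_len(n_trials), color = feats$color,
                   shape = feats$shape, stimulus = .STIMULI[idx])
  })
}

try_balanced_walk <- function(n, no_repeats) {
  permitted <- matrix(TRUE, 4L, 4L)
  if (no_repeats) diag(permitted) <- FALSE
  m <- n - 1L                    # transitions
  n_cells <- sum(permitted)
  base <- m %/% n_cells
  start <- sample.int(4L, 1L)
  end <- sample.int(4L, 1L)
  if (no_repeats && start == end) return(NULL) # deficient cell must be permitted

  quota <- n %/% 4L
  out_deg <- rep(quota, 4L); out_deg[end] <- out_deg[end] - 1L
  in_deg <- rep(quota, 4L); in_deg[start] <- in_deg[start] - 1L
  row_extra <- out_deg - base * rowSums(permitted)
  col_extra <- in_deg - base * colSums(permitted)
  if (any(row_extra < 0L) || any(col_extra < 0L)) return(NULL)

  counts <- matrix(0L, 4L, 4L)
  counts[permitted] <- base
  extra <- assign_extras(row_extra, col_extra, permitted)
  if (is.null(extra)) return(NULL)
  counts <- counts + extra
  if (any(counts[!permitted] > 0L)) return(NULL)

  walk <- hierholzer_path(counts, start)
  if (is.null(walk) || length(walk) != n) return(NULL)
  walk
}

# 0/1 matrix with given margins restricted to permitted cells; greedy
# largest-remaining-first with random tie-breaks.
assign_extras <- function(row_extra, col_extra, permitted) {
  extra <- matrix(0L, 4L, 4L)
  for (u in sample(order(row_extra, decreasing = TRUE))) {
    need <- row_extra[u]
    if (need == 0L) next
    avail <- which(permitted[u, ] & col_extra > 0L)
    if (length(avail) < need) return(NULL)
    pick <- avail[order(-col_extra[avail], sample.int(length(avail)))][seq_len(need)]
    extra[u, pick] <- 1L
    col_extra[pick] <- col_extra[pick] - 1L
  }
  if (any(col_extra != 0L)) return(NULL)
  extra
}

# Randomized Hierholzer traversal of the directed multigraph given by edge
# counts, starting at `start`; returns the vertex sequence or NULL.
hierholzer_path <- function(counts, start) {
  m <- sum(counts)
  stack <- integer(m + 1L); top <- 1L; stack[1L] <- start
  path <- integer(m + 1L); plen <- 0L
  while (top > 0L) {
    v <- stack[top]
    nxt <- which(counts[v, ] > 0L)
    if (length(nxt) == 0L) {
      plen <- plen + 1L; path[plen] <- v
      top <- top - 1L
    } else {
      w <- if (length(nxt) == 1L) nxt else sample(nxt, 1L, prob = counts[v, nxt])
      counts[v, w] <- counts[v, w] - 1L
      top <- top + 1L; stack[top] <- w
    }
  }
  if (sum(counts) > 0L) return(NULL)   # disconnected: edges left over
  rev(path[seq_len(plen)])
}

#' Check balance properties of a stimulus sequence
#'
#' @param sequence A tibble from [generate_trial_sequence()].
#' @param no_repeats Were repeats excluded when generating?
#' @return List with `stimulus_counts`, `transition_counts` (4x4 matrix),
#'   `stimulus_spread` and `transition_spread` (max minus min over counted
#'   cells).
#' @export
sequence_balance <- function(sequence, no_repeats = FALSE) {
  idx <- match(sequence$stimulus, .STIMULI)
  stim <- tabulate(idx, 4L)
  trans <- matrix(0L, 4L, 4L, dimnames = list(.STIMULI, .STIMULI))
  for (t in seq_along(idx)[-1L]) {
    trans[idx[t - 1L], idx[t]] <- trans[idx[t - 1L], idx[t]] + 1L
  }
  cells <- if (no_repeats) trans[row(trans) != col(trans)] else as.vector(trans)
  list(stimulus_counts = stats::setNames(stim, .STIMULI),
       transition_counts = trans,
       stimulus_spread = diff(range(stim)),
       transition_spread = diff(range(cells)))
}

#' Write a stimulus sequence to CSV
#'
#' @param sequence A tibble from [generate_trial_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(sequence, path) {
  readr::write_csv(sequence[, c("trial", "color", "shape")], path)
  invisible(path)
}
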