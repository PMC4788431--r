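# Scoring of motor configuration patterns: adjacency and symmetry bonuses,
# the six pattern classes, and the feature-relabeling group used for
# counterbalancing.

#' Adjacency bonus of a structure view
#'
#' A task-set is "grouped" when the two fingers it requires are physically
#' adjacent (positions differing by exactly 1 in the left-to-right order).
#' The adjacency bonus `a` counts grouped task-sets, so `a` is 0, 1, or 2.
#'
#' @param view A [structure_view()].
#' @return Integer adjacency bonus in 0--2.
#' @examples
#' a12_34 <- contingency_assignment(c(1, 2, 3, 4)) # TS(c1)->{F1,F2}, TS(c2)->{F3,F4}
#' adjacency_bonus(structure_view(a12_34, "color")) # 2
#' @export
adjacency_bonus <- function(view) {
  ts <- task_sets(view)
  sum(vapply(ts, function(m) abs(m[1L] - m[2L]) == 1L, logical(1)))
}

#' Symmetry bonus of a structure view
#'
#' The symmetry bonus `s` is 1 when the two task-sets impose the same
#' left-right arrangement of the stimulus-dimension features: ordering the
#' two stimulus features identically in both task-sets, the first feature's
#' finger lies on the same side of the second feature's finger in both.
#' Otherwise `s` is 0.
#'
#' @inheritParams adjacency_bonus
#' @return Integer 0 or 1.
#' @export
symmetry_bonus <- function(view) {
  ts <- task_sets(view)
  o1 <- ts[[1L]][1L] < ts[[1L]][2L]
  o2 <- ts[[2L]][1L] < ts[[2L]][2L]
  as.integer(o1 == o2)
}

.PATTERN_LABELS <- list(
  "2.0" = c(P1 = 2L, P2 = 0L),
  "1.0" = c(P3 = 1L, P4 = 0L),
  "2.1" = c(P5 = 2L, P6 = 1L)
)

#' Classify a structure view into one of the six motor pattern classes
#'
#' Every assignment has two views (color- or shape-as-context); their
#' adjacency bonuses always form one of the unordered pairs \{2,0\}, \{1,0\}
#' or \{2,1\}, and the two views of one assignment never induce the same
#' finger partition. The six classes are the sibling pairs (P1, P2), (P3, P4)
#' and (P5, P6): P1/P3/P5 designate the higher-adjacency view of each pair,
#' P2/P4/P6 its sibling. Within the \{2,1\} pair the `a = 2` view is labeled
#' P5 by convention.
#'
#' @inheritParams adjacency_bonus
#' @return A `motorstruct_pattern_score`: list with `class` (`"P1"`..`"P6"`),
#'   `a` (this view's adjacency bonus), `a_sibling`, and `s` (symmetry bonus).
#' @export
classify_pattern <- function(view) {
  a <- adjacency_bonus(view)
  a_sib <- adjacency_bonus(sibling_view(view))
  key <- paste(max(a, a_sib), min(a, a_sib), sep = ".")
  labs <- .PATTERN_LABELS[[key]]
  if (is.null(labs)) stop("impossible adjacency pair: ", key, call. = FALSE)
  structure(
    list(class = names(labs)[match(a, labs)], a = a, a_sibling = a_sib,
         s = symmetry_bonus(view)),
    class = "motorstruct_pattern_score"
  )
}

#' @export
print.motorstruct_pattern_score <- function(x, ...) {
  cat(sprintf("<pattern %s> a = %d (sibling a = %d), s = %d\n",
              x$class, x$a, x$a_sibling, x$s))
  invisible(x)
}

# --- feature-relabeling group ------------------------------------------------

swap_colors <- function(view) {
  a <- view$assignment
  nm <- names(a)
  names(a) <- paste0(ifelse(startsWith(nm, "c1"), "c2", "c1"), substr(nm, 3L, 5L))
  structure_view(contingency_assignment(a), view$context)
}

swap_shapes <- function(view) {
  a <- view$assignment
  nm <- names(a)
  names(a) <- paste0(substr(nm, 1L, 3L), ifelse(endsWith(nm, "s1"), "s2", "s1"))
  structure_view(contingency_assignment(a), view$context)
}

exchange_dimensions <- function(view) {
  a <- view$assignment
  f <- stimulus_features(names(a))
  # stimulus (ci, sj) takes the finger of old (cj, si): color/shape roles swap
  names(a) <- paste0("c", substr(f$shape, 2L, 2L), ".s", substr(f$color, 2L, 2L))
  structure_view(contingency_assignment(a), other_dimension(view$context))
}

#' The eight-element feature-relabeling group applied to a view
#'
#' Generators: swapping the two color labels, swapping the two shape labels,
#' and exchanging the roles of the color and shape dimensions (which also
#' swaps the context role). Views in the same orbit describe the same motor
#' configuration pattern up to counterbalancing.
#'
#' @inheritParams adjacency_bonus
#' @return List of 8 `motorstruct_view`s (the orbit, including `view` itself).
#' @export
relabelings <- function(view) {
  out <- vector("list", 8L)
  i <- 1L
  for (ex in c(FALSE, TRUE)) {
    v1 <- if (ex) exchange_dimensions(view) else view
    for (sc in c(FALSE, TRUE)) {
      v2 <- if (sc) swap_colors(v1) else v1
      for (ss in c(FALSE, TRUE)) {
        out[[i]] <- if (ss) swap_shapes(v2) else v2
        i <- i + 1L
      }
    }
  }
  out
}

view_key <- function(view) {
  paste(view$context, paste(view$assignment, collapse = ""), sep = ":")
}

all_views <- function() {
  perms <- permutations_of_four()
  out <- vector("list", 48L)
  i <- 1L
  for (ctx in c("color", "shape")) {
    for (p in seq_len(nrow(perms))) {
      out[[i]] <- structure_view(contingency_assignment(perms[p, ]), ctx)
      i <- i + 1L
    }
  }
  out
}

permutations_of_four <- function() {
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  dimnames(g) <- NULL
  g[apply(g, 1L, function(r) length(unique(r)) == 4L), , drop = FALSE]
}

#' Enumerate the motor pattern classes
#'
#' Enumerates all 24 stimulus-finger bijections under both context choices
#' (48 views), groups views into orbits of the feature-relabeling group
#' ([relabelings()]), and tabulates the resulting classes. Counting patterns
#' up to color permutation, shape permutation and exchange of the two
#' dimensions' roles yields exactly 6 classes of 8 views each.
#'
#' @return A `motorstruct_pattern_table`: list with `classes`, a tibble with
#'   one row per class (`class`, `a`, `a_sibling`, `s`, `n_views`, and a
#'   `representative` list-column of one view per class), and `views`, the
#'   full 48-row tibble (`key`, `context`, `class`, `a`, `a_sibling`, `s`,
#'   `orbit`, `view` list-column).
#' @export
enumerate_pattern_classes <- function() {
  views <- all_views()
  rows <- lapply(views, function(v) {
    ps <- classify_pattern(v)
    orbit <- min(vapply(relabelings(v), view_key, ""))
    tibble::tibble(key = view_key(v), context = v$context, class = ps$class,
                   a = ps$a, a_sibling = ps$a_sibling, s = ps$s, orbit = orbit)
  })
  tab <- dplyr::bind_rows(rows)
  tab$view <- views
  cls <- tab |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      a = unique(.data$a), a_sibling = unique(.data$a_sibling),
      s = min(.data$s), n_views = dplyr::n(),
      n_orbits = dplyr::n_distinct(.data$orbit),
      representative = list(.data$view[[1L]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$class)
  structure(list(classes = cls, views = tab), class = "motorstruct_pattern_table")
}

#' @export
print.motorstruct_pattern_table <- function(x, ...) {
  cat("<motor pattern classes>", nrow(x$classes), "classes over",
      nrow(x$views), "views\n")
  print(x$classes[, c("class", "a", "a_sibling", "n_views")])
  invisible(x)
}

#' Representative assignments of a pattern class with color as context
#'
#' Used to counterbalance simulation runs: returns every assignment whose
#' color-as-context view belongs to the requested class.
#'
#' @param class One of `"P1"`..`"P6"`.
#' @return List of `motorstruct_view`s (context `"color"`), typically 4.
#' @export
class_representatives <- function(class) {
  stopifnot(class %in% paste0("P", 1:6))
  views <- all_views()
  keep <- vapply(views, function(v) {
    v$context == "color" && classify_pattern(v)$class == class
  }, logical(1))
  views[keep]
}
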