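# Core task-design objects: the 2x2 stimulus set, finger assignments, and
# structure views (which feature dimension plays the context role).

# Stimulus identifiers are "<color>.<shape>" over two features per dimension.
.COLORS <- c("c1", "c2")
.SHAPES <- c("s1", "s2")
.STIMULI <- c("c1.s1", "c1.s2", "c2.s1", "c2.s2")
.FINGERS <- c("F1", "F2", "F3", "F4")

#' Create a stimulus-to-finger contingency assignment
#'
#' An assignment is a bijection from the four two-feature stimuli (two colors
#' crossed with two shapes) to the four response fingers, ordered left to
#' right (F1--F4). The correct response on a trial is the finger assigned to
#' the presented stimulus.
#'
#' @param fingers Fingers for the four stimuli, in the order
#'   `c1.s1, c1.s2, c2.s1, c2.s2`, either as integer positions 1--4 or as
#'   labels `"F1"`--`"F4"`. May be named by stimulus id, in which case names
#'   are used to match.
#' @return A `motorstruct_assignment`: a named integer vector of finger
#'   positions, one per stimulus.
#' @examples
#' contingency_assignment(c(1, 2, 3, 4))
#' contingency_assignment(c(c2.s1 = "F1", c2.s2 = "F2", c1.s1 = "F3", c1.s2 = "F4"))
#' @export
contingency_assignment <- function(fingers) {
  if (is.character(fingers)) {
    pos <- match(fingers, .FINGERS)
    if (anyNA(pos)) stop("unknown finger label; expected F1..F4", call. = FALSE)
    names(pos) <- names(fingers)
    fingers <- pos
  }
  fingers <- stats::setNames(as.integer(fingers), names(fingers))
  if (length(fingers) != 4L) {
    stop("an assignment needs exactly 4 stimulus-finger pairs", call. = FALSE)
  }
  if (!is.null(names(fingers)) && !all(names(fingers) == "")) {
    if (!setequal(names(fingers), .STIMULI)) {
      stop("stimulus names must be exactly ", paste(.STIMULI, collapse = ", "),
           call. = FALSE)
    }
    fingers <- fingers[.STIMULI]
  } else {
    names(fingers) <- .STIMULI
  }
  validate_assignment(fingers)
  structure(fingers, class = "motorstruct_assignment")
}

validate_assignment <- function(x) {
  if (anyNA(x) || !setequal(x, 1:4)) {
    stop("invalid assignment: stimulus-finger map must be a bijection onto fingers 1..4",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.motorstruct_assignment <- function(x, ...) {
  cat("<contingency assignment>\n")
  cat(paste0("  ", names(x), " -> ", .FINGERS[x], collapse = "\n"), "\n")
  invisible(x)
}

#' View an assignment under a choice of context dimension
#'
#' A structure view fixes which of the two feature dimensions serves as the
#' context (cueing a task-set) and which as the stimulus (selecting the
#' action within the task-set). Each assignment therefore has exactly two
#' views -- the color-as-context and shape-as-context structures -- and each
#' view induces two task-sets mapping the two stimulus-dimension features to
#' two distinct fingers.
#'
#' @param assignment A [contingency_assignment()].
#' @param context `"color"` or `"shape"`: the dimension cueing task-sets.
#' @return A `motorstruct_view` with elements `assignment` and `context`.
#' @seealso [task_sets()], [adjacency_bonus()], [classify_pattern()]
#' @export
structure_view <- function(assignment, context = c("color", "shape")) {
  if (!inherits(assignment, "motorstruct_assignment")) {
    assignment <- contingency_assignment(assignment)
  }
  context <- match.arg(context)
  structure(list(assignment = assignment, context = context),
            class = "motorstruct_view")
}

#' @export
print.motorstruct_view <- function(x, ...) {
  cat("<structure view> context:", x$context, "\n")
  ts <- task_sets(x)
  for (ctx in names(ts)) {
    cat("  TS[", ctx, "]: ", paste0(names(ts[[ctx]]), "->", .FINGERS[ts[[ctx]]],
                                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

other_dimension <- function(context) if (context == "color") "shape" else "color"

#' Sibling view of a structure view
#'
#' The same assignment re-grouped under the other context dimension.
#' @param view A [structure_view()].
#' @return The `motorstruct_view` with the roles of the two dimensions swapped.
#' @export
sibling_view <- function(view) {
  structure_view(view$assignment, other_dimension(view$context))
}

stimulus_features <- function(stimuli) {
  parts <- strsplit(stimuli, ".", fixed = TRUE)
  list(color = vapply(parts, `[`, "", 1L), shape = vapply(parts, `[`, "", 2L))
}

#' Task-sets induced by a structure view
#'
#' @param view A [structure_view()].
#' @return A named list with one element per context feature; each element is
#'   a named integer vector mapping the two stimulus-dimension features to
#'   finger positions.
#' @export
task_sets <- function(view) {
  stopifnot(inherits(view, "motorstruct_view"))
  feats <- stimulus_features(names(view$assignment))
  ctx <- feats[[view$context]]
  stim <- feats[[other_dimension(view$context)]]
  out <- lapply(split(seq_along(ctx), ctx), function(i) {
    ts <- as.integer(view$assignment[i])
    names(ts) <- stim[i]
    ts[order(names(ts))]
  })
  out[order(names(out))]
}

#' Serialize / deserialize a structure view as JSON
#'
#' The wire format is `{"map": {"c1,s1": "F3", ...}, "context": "color"}`.
#'
#' @param view A [structure_view()].
#' @param json A JSON string or path to a JSON file.
#' @return `view_to_json()` a JSON string; `view_from_json()` a
#'   `motorstruct_view`.
#' @export
view_to_json <- function(view) {
  stopifnot(inherits(view, "motorstruct_view"))
  map <- as.list(.FINGERS[view$assignment])
  names(map) <- sub(".", ",", names(view$assignment), fixed = TRUE)
  jsonlite::toJSON(list(map = map, context = view$context), auto_unbox = TRUE)
}

#' @rdname view_to_json
#' @export
view_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  fingers <- unlist(x$map)
  names(fingers) <- sub(",", ".", names(fingers), fixed = TRUE)
  structure_view(contingency_assignment(fingers), x$context)
}
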