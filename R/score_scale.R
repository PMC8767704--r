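#' The canonical 9-class ordinal hairiness scale
#'
#' Cotton leaf hairiness is scored visually on an ascending, non-linear
#' ordinal scale running from `"1"` (glabrous, hairless) to `"5+"` (pilose,
#' very hairy), with seven intermediate scores.  The canonical label order
#' is `"1" < "2" < "3" < "3/4" < "4" < "4/4+" < "4+" < "5" < "5+"`.
#'
#' Only the ordering and adjacency of classes are ever used by this
#' package (tie-breaking in leaf-level aggregation, adjacent-class error
#' analysis); no numeric hairiness value is attached to a class, and the
#' ordinal distance between classes is their rank difference.
#'
#' @return Character vector of the 9 labels in ascending order.
#' @export
#' @examples
#' score_labels()
#' match("3/4", score_labels()) - 1L  # rank 3
score_labels <- function() {
  c("1", "2", "3", "3/4", "4", "4/4+", "4+", "5", "5+")
}

#' Construct a score class from a label or a rank
#'
#' A score class is represented as a `leafhair_score` object: a character
#' label carrying an integer `rank` attribute in `[0, 8]`, the position of
#' the label on the canonical scale.  The label/rank mapping is bijective.
#'
#' @param label One of the labels returned by [score_labels()], or the
#'   print variant `"4/4"` which is accepted as an alias of `"4/4+"` and
#'   normalised.
#' @param rank Alternative to `label`: integer rank in `[0, 8]`.
#' @return A `leafhair_score` object.
#' @seealso [parse_score_label()], [score_rank()]
#' @export
score_class <- function(label = NULL, rank = NULL) {
  labs <- score_labels()
  if (is.null(label) && is.null(rank))
    stop("provide either `label` or `rank`")
  if (is.null(label)) {
    rank <- as.integer(rank)
    if (length(rank) != 1L || is.na(rank) || rank < 0L || rank > 8L)
      stop("`rank` must be a single integer in [0, 8], got: ", rank)
    label <- labs[rank + 1L]
  } else {
    label <- normalize_score_label(label)
    rank <- match(label, labs) - 1L
  }
  structure(label, rank = rank, class = "leafhair_score")
}

# "4/4" appears in one of the dataset summary tables as a print variant of
# the canonical "4/4+"; accept it on input, emit the canonical form.
normalize_score_label <- function(text) {
  text <- trimws(as.character(text))
  text[text == "4/4"] <- "4/4+"
  bad <- !(text %in% score_labels())
  if (any(bad)) {
    stop("unknown score label(s): ", paste(sQuote(unique(text[bad])), collapse = ", "),
         "; valid labels are: ", paste(sQuote(score_labels()), collapse = ", "),
         " (and the alias '4/4' for '4/4+')")
  }
  text
}

#' Parse a score label into a score class
#'
#' @param text A single trimmed label token.  The alias `"4/4"` maps to
#'   `"4/4+"`.  Unknown tokens are rejected with a message naming the
#'   offending token and listing the valid labels.
#' @return A `leafhair_score` object.
#' @export
#' @examples
#' score_rank(parse_score_label("3/4"))  # 3
#' parse_score_label("4/4")              # normalised to "4/4+", rank 5
parse_score_label <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single token")
  score_class(label = text)
}

#' Rank of a score class or label vector
#'
#' Vectorised: accepts a `leafhair_score` object or a character vector of
#' labels (aliases allowed) and returns integer ranks in `[0, 8]`.
#'
#' @param x Score class object or character vector of labels.
#' @return Integer vector of ranks.
#' @export
score_rank <- function(x) {
  if (inherits(x, "leafhair_score")) return(attr(x, "rank"))
  match(normalize_score_label(x), score_labels()) - 1L
}

#' @export
print.leafhair_score <- function(x, ...) {
  cat(sprintf("<score %s (rank %d of 0..8)>\n", unclass(x), attr(x, "rank")))
  invisible(x)
}

#' @export
format.leafhair_score <- function(x, ...) unclass(x)

#' Ordered factor over the canonical scale
#'
#' Convenience used by confusion matrices and reports: converts label
#' vectors (aliases allowed) into an ordered factor whose levels are the
#' canonical scale, optionally restricted to the classes present.
#'
#' @param labels Character vector of score labels.
#' @param drop If `TRUE`, keep only levels present in `labels`.
#' @return An ordered factor.
#' @export
score_factor <- function(labels, drop = FALSE) {
  labels <- normalize_score_label(labels)
  lv <- score_labels()
  if (drop) lv <- lv[lv %in% labels]
  factor(labels, levels = lv, ordered = TRUE)
}
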