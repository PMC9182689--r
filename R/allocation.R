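#' Rank subgroups by modeled screening benefit
#'
#' Descending by score, with deterministic tie-breaks: larger subgroup
#' first, then lexicographic key.
#'
#' @param scores data.frame with columns `subgroup` (key label), `score`
#'   (benefit per screen or per patient), and `size` (screenable count).
#' @return the data.frame reordered, with a `rank` column.
#' @export
rank_subgroups <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("subgroup", "score", "size") %in% names(scores)),
            all(is.finite(scores$score)))
  ord <- order(-scores$score, -scores$size, scores$subgroup)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Greedy allocation of a screening budget across subgroups
#'
#' Saturates subgroups in rank order: the highest-scoring subgroup whose
#' score strictly exceeds the worthwhileness threshold T receives
#' screens up to its size, then the next, until the budget is exhausted
#' or the next score falls to T or below. With a per-screen-constant
#' benefit the objective is linear with box constraints, so this greedy
#' rule is optimal.
#'
#' @param scores data.frame as in [rank_subgroups()].
#' @param budget total screens available (non-negative integer).
#' @param threshold T, minimal score for a screen to be worthwhile
#'   (same units as `score`); subgroups with score <= T get nothing.
#' @param mode unit of `score`: "per_screen" (days/screen) or
#'   "per_patient" (years/patient); metadata only.
#' @return object of class `allocation_result`: data.frame of ranked
#'   subgroups with `screens` assigned, plus attributes `total_screens`,
#'   `total_benefit`, `budget`, `threshold`, `mode`.
#' @examples
#' sc <- data.frame(subgroup = c("a", "b", "c"), score = c(.6, .3, .05),
#'                  size = c(1000, 2000, 5000))
#' allocate_screens(sc, budget = 2500, threshold = 0.1)
#' @export
allocate_screens <- function(scores, budget, threshold = 0,
                             mode = c("per_screen", "per_patient")) {
  mode <- match.arg(mode)
  stopifnot(budget >= 0, budget == floor(budget),
            all(scores$size >= 0), all(scores$size == floor(scores$size)))
  ranked <- rank_subgroups(scores)
  ranked$screens <- 0
  remaining <- budget
  for (i in seq_len(nrow(ranked))) {
    if (remaining <= 0) break
    if (ranked$score[i] <= threshold) break
    take <- min(ranked$size[i], remaining)
    ranked$screens[i] <- take
    remaining <- remaining - take
  }
  structure(ranked,
            class = c("allocation_result", "data.frame"),
            total_screens = sum(ranked$screens),
            total_benefit = sum(ranked$screens * ranked$score),
            budget = budget, threshold = threshold, mode = mode)
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> budget %d, threshold %g (%s)\n",
              attr(x, "budget"), attr(x, "threshold"), attr(x, "mode")))
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("screens used: %d; total projected benefit: %g\n",
              attr(x, "total_screens"), attr(x, "total_benefit")))
  invisible(x)
}
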