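#' Quantile-based ability groups for integer raw scores
#'
#' Groups a score vector into `G` ability groups by empirical quantiles.
#' Because raw number-correct scores are integers with heavy ties,
#' interpolation-based quantiles are ill-defined; the rule used here is fully
#' deterministic: breakpoint k (k = 1..G-1) is the smallest observed score
#' whose empirical CDF reaches k/G, and a person is assigned to the first
#' group whose upper breakpoint is at least their score. Ties are never
#' split, so fewer than `G` groups can be realized.
#'
#' @param scores numeric vector of (typically integer) scores.
#' @param G requested number of groups (>= 2).
#' @return An `ability_grouping` object: `G_requested`, `breakpoints`
#'   (G - 1 upper breakpoints), `labels` (group index per person, a monotone
#'   function of score), and `G_realized` (number of non-empty groups).
#' @export
ability_groups <- function(scores, G) {
  if (length(scores) == 0) stop_validation("empty score vector")
  G <- as.integer(G)
  if (is.na(G) || G < 2) stop_validation("G must be >= 2")
  r <- rle(sort(scores))
  cum <- cumsum(r$lengths) / length(scores)
  bk <- vapply(seq_len(G - 1L), function(k) r$values[which(cum >= k / G)[1L]],
               numeric(1))
  labels <- group_labels(scores, bk)
  structure(list(G_requested = G, breakpoints = bk, labels = labels,
                 G_realized = length(unique(labels))),
            class = "ability_grouping")
}

# Assign scores to groups given upper breakpoints: group = 1 + number of
# breakpoints strictly below the score.
group_labels <- function(scores, breakpoints) {
  lab <- rep(1L, length(scores))
  for (b in breakpoints) lab <- lab + (scores > b)
  lab
}

#' @export
print.ability_grouping <- function(x, ...) {
  cat(sprintf("ability_grouping: %d groups requested, %d realized; breakpoints %s\n",
              x$G_requested, x$G_realized,
              paste(format(x$breakpoints), collapse = ", ")))
  invisible(x)
}
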