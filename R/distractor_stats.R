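#' Screen distractors by choice frequency
#'
#' A distractor is retained when it was chosen by at least `min_rel_freq` of
#' all participants (inclusive boundary, 5% by default). Distractors failing
#' the screen are excluded from all downstream item-level statistics.
#'
#' @param scored a [score_responses()] result.
#' @param item item name or index.
#' @param min_rel_freq minimum relative choice frequency.
#' @return A list with `retained` (distractor slots), `retained_codes`,
#'   `n_below` (count failing the screen), `counts`, and `rel_freq`.
#' @export
screen_distractors <- function(scored, item, min_rel_freq = 0.05) {
  j <- item_index(scored, item)
  m <- scored$n_distractors[[j]]
  d <- scored$distractor[, j]
  counts <- tabulate(d[!is.na(d)], nbins = m)
  rel <- counts / length(scored$persons)
  keep <- rel >= min_rel_freq
  list(retained = which(keep),
       retained_codes = scored$distractor_codes[[j]][keep],
       n_below = sum(!keep), counts = counts, rel_freq = rel)
}

# Shared setup for the item-level effect sizes: non-solvers of item j who
# chose a retained distractor. Returns NULL-value results with an na_reason
# when the table is degenerate.
nonsolver_table <- function(scored, j, min_rel_freq) {
  scr <- screen_distractors(scored, j, min_rel_freq)
  ns <- nonsolver_view(scored, j)
  if (length(ns$total) == 0)
    return(list(na = "no_nonsolvers", screen = scr))
  if (length(scr$retained) < 2)
    return(list(na = "insufficient_distractors", screen = scr))
  in_tab <- ns$distractor %in% scr$retained
  list(na = NULL, screen = scr, ns = ns,
       d = ns$distractor[in_tab], total = ns$total[in_tab],
       all_ns_total = ns$total)
}

#' Cohen's omega over ability groups and distractor choice
#'
#' Builds the contingency table of retained distractor (rows) by ability
#' group (columns) over the non-solvers of the item, and returns
#' omega_G = sqrt(Pearson chi-squared / n), where n is the number of
#' non-solvers in the table. Group breakpoints are quantiles of the
#' non-solver total-score distribution by default. All-zero rows and columns
#' are dropped before the chi-squared; `NA` (with an `na_reason` attribute)
#' is returned when fewer than two rows or two realized columns remain, when
#' fewer than two distractors survive the 5% screen, or when the item has no
#' non-solvers.
#'
#' @inheritParams screen_distractors
#' @param G number of ability groups.
#' @param grouping population whose score quantiles define the groups:
#'   non-solvers of the item (default) or all persons.
#' @return omega_G (>= 0), or `NA` with attribute `na_reason`.
#' @export
cohen_omega_g <- function(scored, item, G, min_rel_freq = 0.05,
                          grouping = c("nonsolvers", "all")) {
  grouping <- match.arg(grouping)
  j <- item_index(scored, item)
  res <- omega_g_detail(scored, j, G, min_rel_freq, grouping)
  out <- res$value
  if (is.na(out)) attr(out, "na_reason") <- res$na_reason
  out
}

omega_g_detail <- function(scored, j, G, min_rel_freq, grouping = "nonsolvers") {
  nt <- nonsolver_table(scored, j, min_rel_freq)
  if (!is.null(nt$na))
    return(list(value = NA_real_, na_reason = nt$na, G_realized = NA_integer_))
  base_scores <- if (grouping == "all") scored$total else nt$all_ns_total
  grp <- ability_groups(base_scores, G)
  omega_core(nt$d, nt$total, nt$screen$retained, grp$breakpoints, G)
}

# Core of omega_G on pre-restricted vectors: d = retained-distractor slot per
# table person, y = their total scores.
omega_core <- function(d, y, retained, breakpoints, G) {
  lab <- group_labels(y, breakpoints)
  idx <- (match(d, retained) - 1L) * G + lab
  tab <- matrix(tabulate(idx, length(retained) * G), nrow = G)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  g_real <- nrow(tab) # rows are groups here
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(value = NA_real_, na_reason = "degenerate_groups",
                G_realized = g_real))
  chisq <- pearson_chisq(tab)
  n <- sum(tab)
  list(value = sqrt(chisq / n), na_reason = NA_character_,
       chisq = chisq, n = n, G_realized = g_real)
}

# Pearson chi-squared of a contingency table, no continuity correction
# (effect-size use, not testing).
pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Canonical correlation between distractor choice and non-solver scores
#'
#' Among non-solvers who chose a retained distractor, the choice of each of
#' the K retained distractors is coded as a binary indicator variable; one
#' indicator is dropped because the K indicators sum to one (which would make
#' the indicator correlation matrix singular in the Cholesky step). With
#' r12 the correlations between the remaining indicators and the total
#' score, and H1 the Cholesky factor of their correlation matrix, R_CC is
#' the single singular value of W = r12' H1^{-1}. The result does not depend
#' on which indicator is dropped and equals the correlation ratio eta of the
#' one-way layout of scores over distractor groups.
#'
#' @inheritParams screen_distractors
#' @return R_CC in [0, 1], or `NA` with attribute `na_reason` when fewer than
#'   two distractors survive the screen, the item has no non-solvers, or the
#'   scores carry no variance.
#' @export
canonical_correlation <- function(scored, item, min_rel_freq = 0.05) {
  j <- item_index(scored, item)
  res <- r_cc_detail(scored, j, min_rel_freq)
  out <- res$value
  if (is.na(out)) attr(out, "na_reason") <- res$na_reason
  out
}

r_cc_detail <- function(scored, j, min_rel_freq, drop = NULL) {
  nt <- nonsolver_table(scored, j, min_rel_freq)
  if (!is.null(nt$na)) return(list(value = NA_real_, na_reason = nt$na))
  r_cc_core(nt$d, nt$total, nt$screen$retained, drop)
}

# Core of R_CC on pre-restricted vectors (non-solvers choosing a retained
# distractor): Eq.-style canonical correlation with drop-one indicator coding.
r_cc_core <- function(d, y, retained, drop = NULL) {
  n <- length(y)
  if (n < 2 || stats::sd(y) == 0)
    return(list(value = NA_real_, na_reason = "zero_variance"))
  if (is.null(drop)) drop <- length(retained) # drop the last retained indicator
  idx <- match(d, retained[-drop])
  x1 <- matrix(0, n, length(retained) - 1L)
  sel <- which(!is.na(idx))
  x1[cbind(sel, idx[sel])] <- 1
  cs <- colSums(x1)
  if (any(cs == 0) || any(cs == n))
    return(list(value = NA_real_, na_reason = "zero_variance"))
  r12 <- stats::cor(x1, y)
  h1 <- tryCatch(chol(stats::cor(x1)), error = function(e) NULL)
  if (is.null(h1)) return(list(value = NA_real_, na_reason = "zero_variance"))
  w <- crossprod(r12, solve(h1))
  val <- svd(w)$d[1]
  list(value = min(val, 1), na_reason = NA_character_)
}

# Resolve a distractor given by code or slot to its slot index for item j.
distractor_slot <- function(scored, j, distractor) {
  codes <- scored$distractor_codes[[j]]
  if (is.character(distractor)) {
    v <- match(distractor, codes)
    if (is.na(v)) stop_validation("unknown distractor '%s' for item '%s'",
                                  distractor, scored$items[j])
  } else {
    v <- as.integer(distractor)
    if (is.na(v) || v < 1 || v > length(codes))
      stop_validation("distractor slot out of range: %s", distractor)
  }
  v
}

#' Point-biserial correlation of distractor choice with test performance
#'
#' `point_biserial_d` contrasts the participants who chose distractor D with
#' all participants: (M_D - M) / S * sqrt(P_D / (1 - P_D)), where M_D is the
#' mean total score of the D choosers, M and S the mean and (population)
#' standard deviation of all total scores, and P_D the proportion choosing D.
#' This equals the Pearson correlation between the {chose D} indicator and
#' the total score.
#'
#' @inheritParams screen_distractors
#' @param distractor distractor code (character) or slot (integer).
#' @return The point-biserial correlation in [-1, 1], or `NA` when the
#'   choice proportion is 0 or 1 or the scores have no variance.
#' @export
point_biserial_d <- function(scored, item, distractor) {
  j <- item_index(scored, item)
  v <- distractor_slot(scored, j, distractor)
  ind <- !is.na(scored$distractor[, j]) & scored$distractor[, j] == v
  pb_core(scored$total, ind)
}

# Point-biserial of a binary indicator against scores; with the population
# standard deviation this is exactly the Pearson correlation.
pb_core <- function(y, ind) {
  p <- mean(ind)
  s <- sd_pop(y)
  if (length(y) < 2 || p == 0 || p == 1 || s == 0) return(NA_real_)
  (mean(y[ind]) - mean(y)) / s * sqrt(p / (1 - p))
}

#' @rdname point_biserial_d
#' @details `point_biserial_dc` restricts the contrast to the participants
#'   who either chose D or solved the item: (M_D - M_DC) / S_DC *
#'   sqrt(P_D / P_C) with all quantities computed within that subgroup. It
#'   equals the Pearson correlation between the {chose D} indicator and the
#'   total score restricted to the subgroup.
#' @export
point_biserial_dc <- function(scored, item, distractor) {
  j <- item_index(scored, item)
  v <- distractor_slot(scored, j, distractor)
  chose_d <- !is.na(scored$distractor[, j]) & scored$distractor[, j] == v
  sub <- chose_d | scored$correct[, j]
  pb_core(scored$total[sub], chose_d[sub])
}

#' Haladyna-Downing per-distractor omega
#'
#' Cohen's omega for a single distractor: ability groups are built from the
#' total scores of all participants (`G` equi-distant quantiles), the choice
#' counts of D across the realized groups are tested for goodness-of-fit
#' against the uniform distribution, and omega_D = sqrt(chi-squared / n_D).
#'
#' @inheritParams point_biserial_d
#' @param G number of ability groups (default 5).
#' @return omega_D >= 0, or `NA` when D has no choosers or fewer than two
#'   groups are realized.
#' @export
haladyna_omega_d <- function(scored, item, distractor, G = 5) {
  j <- item_index(scored, item)
  v <- distractor_slot(scored, j, distractor)
  grp <- ability_groups(scored$total, G)
  if (grp$G_realized < 2) return(NA_real_)
  realized <- sort(unique(grp$labels))
  chose <- !is.na(scored$distractor[, j]) & scored$distractor[, j] == v
  n_d <- sum(chose)
  if (n_d == 0) return(NA_real_)
  counts <- vapply(realized, function(g) sum(chose & grp$labels == g), numeric(1))
  e <- n_d / length(realized)
  sqrt(sum((counts - e)^2 / e) / n_d)
}

#' Goodman-Kruskal gamma for rising selection ratios
#'
#' For the participants who either solved the item or chose distractor D, a
#' 2 x J contingency table is formed with J the observed rest-score values
#' (scores on all other items). For each score level the probability of
#' choosing the correct option, p_j, is the correct-row count over the
#' column sum. Gamma compares p across all level pairs j < j': pairs with
#' rising p are concordant, falling p discordant, ties are dropped;
#' gamma = (C - D) / (C + D). A value of 1 means the odds of solving versus
#' choosing D rise monotonically with ability.
#'
#' With `weighted = TRUE`, the classic frequency-weighted gamma of the 2 x J
#' table is returned instead (pairs of observations rather than pairs of
#' score levels).
#'
#' @inheritParams point_biserial_d
#' @param weighted weight level pairs by table frequencies.
#' @return gamma in [-1, 1], or `NA` when fewer than two score levels occur
#'   or all pairs tie.
#' @export
goodman_kruskal_gamma <- function(scored, item, distractor, weighted = FALSE) {
  j <- item_index(scored, item)
  v <- distractor_slot(scored, j, distractor)
  chose_d <- !is.na(scored$distractor[, j]) & scored$distractor[, j] == v
  sub <- chose_d | scored$correct[, j]
  if (!any(chose_d) || !any(scored$correct[, j])) return(NA_real_)
  gamma_core(scored$correct[sub, j], scored$rest[sub, j], weighted)
}

# Core of gamma on the restricted persons (solvers of the item or choosers
# of D): corr = solved indicator, rest = rest scores.
gamma_core <- function(corr, rest, weighted = FALSE) {
  lev <- sort(unique(rest))
  jj <- length(lev)
  if (jj < 2) return(NA_real_)
  li <- match(rest, lev)
  n_c <- tabulate(li[corr], jj)
  n_d <- tabulate(li[!corr], jj)
  if (weighted) {
    conc <- 0; disc <- 0
    for (a in seq_len(jj - 1L)) {
      hi <- (a + 1L):jj
      conc <- conc + n_d[a] * sum(n_c[hi])
      disc <- disc + n_c[a] * sum(n_d[hi])
    }
    if (conc + disc == 0) return(NA_real_)
    return((conc - disc) / (conc + disc))
  }
  gamma_tab(n_c, n_d)
}

# Unweighted gamma from per-level counts of correct / distractor choosers
# (levels ordered by score; empty levels are skipped).
gamma_tab <- function(n_c, n_d) {
  pres <- (n_c + n_d) > 0
  p <- n_c[pres] / (n_c[pres] + n_d[pres])
  if (length(p) < 2) return(NA_real_)
  # dif[a, b] = p[b] - p[a]; upper triangle holds pairs with level a < b
  dif <- -outer(p, p, "-")
  up <- upper.tri(dif)
  conc <- sum(dif[up] > 0)
  disc <- sum(dif[up] < 0)
  if (conc + disc == 0) return(NA_real_)
  (conc - disc) / (conc + disc)
}

#' Option-by-ability-group trace table
#'
#' Relative choice frequency of every option (the correct option and each
#' distractor) within each realized ability group, the tabular form of a
#' trace line plot. Frequencies sum to 1 within each group.
#'
#' @inheritParams screen_distractors
#' @param G number of ability groups (default 5).
#' @return A matrix (options x realized groups) of relative frequencies with
#'   option codes as row names; attribute `group_sizes` holds the group
#'   sizes.
#' @export
trace_table <- function(scored, item, G = 5) {
  j <- item_index(scored, item)
  grp <- ability_groups(scored$total, G)
  opt <- ifelse(scored$correct[, j], 0L, scored$distractor[, j])
  m <- scored$n_distractors[[j]]
  tab <- table(factor(opt, levels = 0:m),
               factor(grp$labels, levels = sort(unique(grp$labels))))
  sizes <- colSums(tab)
  out <- sweep(unclass(tab), 2L, sizes, "/")
  rownames(out) <- c(scored$key[[j]], scored$distractor_codes[[j]])
  attr(out, "group_sizes") <- sizes
  out
}
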