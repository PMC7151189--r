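#' Configuration for item analysis
#'
#' @param G_omega group counts for Cohen's omega (default 2 and 5).
#' @param G_d group count for the per-distractor omega and trace tables.
#' @param min_rel_freq choice-frequency screen (default 0.05, inclusive).
#' @param grouping quantile population for omega_G, see [cohen_omega_g()].
#' @param weighted_gamma use the frequency-weighted gamma variant.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(G_omega = c(2L, 5L), G_d = 5L, min_rel_freq = 0.05,
                            grouping = c("nonsolvers", "all"),
                            weighted_gamma = FALSE) {
  grouping <- match.arg(grouping)
  structure(list(G_omega = as.integer(G_omega), G_d = as.integer(G_d),
                 min_rel_freq = min_rel_freq, grouping = grouping,
                 weighted_gamma = weighted_gamma),
            class = "analysis_config")
}

#' Analyze one item
#'
#' Runs the choice-frequency screen, then every statistic on the retained
#' distractors: Cohen's omega_G for each requested group count, the canonical
#' correlation R_CC, and per retained distractor the point-biserials PB_D and
#' PB_DC, the Haladyna-Downing omega_D, and Goodman-Kruskal gamma. Statistics
#' that cannot be computed are `NA` with an enumerated `na_reason`
#' (`insufficient_distractors`, `degenerate_groups`, `zero_variance`,
#' `no_nonsolvers`).
#'
#' @param scored a [score_responses()] result.
#' @param item item name or index.
#' @param config an [analysis_config()].
#' @return An `item_analysis` list; see the field list in the README.
#' @export
analyze_item <- function(scored, item, config = analysis_config()) {
  j <- item_index(scored, item)
  scr <- screen_distractors(scored, j, config$min_rel_freq)
  n_ns <- sum(!scored$correct[, j])

  omega <- stats::setNames(rep(NA_real_, length(config$G_omega)),
                           paste0("omega_", config$G_omega))
  g_real <- stats::setNames(rep(NA_integer_, length(config$G_omega)),
                            names(omega))
  omega_reason <- NA_character_
  for (k in seq_along(config$G_omega)) {
    res <- omega_g_detail(scored, j, config$G_omega[k], config$min_rel_freq,
                          config$grouping)
    omega[k] <- res$value
    g_real[k] <- res$G_realized
    if (is.na(res$value) && is.na(omega_reason)) omega_reason <- res$na_reason
  }
  rcc <- r_cc_detail(scored, j, config$min_rel_freq)

  codes <- scr$retained_codes
  per <- function(f, ...) stats::setNames(
    vapply(scr$retained, function(v) f(scored, j, v, ...), numeric(1)), codes)
  if (length(scr$retained) > 0) {
    pb_d <- per(point_biserial_d)
    pb_dc <- per(point_biserial_dc)
    omega_d <- per(haladyna_omega_d, G = config$G_d)
    gamma <- per(goodman_kruskal_gamma, weighted = config$weighted_gamma)
  } else {
    pb_d <- pb_dc <- omega_d <- gamma <- stats::setNames(numeric(0), character(0))
  }

  na_reason <- if (!is.na(rcc$na_reason)) rcc$na_reason else omega_reason

  structure(list(
    item = scored$items[j],
    n_persons = length(scored$persons),
    n_nonsolvers = n_ns,
    retained_distractors = codes,
    n_retained = length(scr$retained),
    n_below_5pct = scr$n_below,
    rel_freq = stats::setNames(scr$rel_freq, scored$distractor_codes[[j]]),
    omega_by_G = omega,
    groups_realized = g_real,
    r_cc = rcc$value,
    pb_d = pb_d, pb_dc = pb_dc, omega_d = omega_d, gamma = gamma,
    mean_pb_dc = if (any(!is.na(pb_dc))) mean(pb_dc, na.rm = TRUE) else NA_real_,
    mean_gamma = if (any(!is.na(gamma))) mean(gamma, na.rm = TRUE) else NA_real_,
    na_reason = na_reason,
    config = config), class = "item_analysis")
}

#' @export
print.item_analysis <- function(x, ...) {
  cat(sprintf("item %s: %d non-solvers, %d retained distractor(s) (%d below screen)\n",
              x$item, x$n_nonsolvers, x$n_retained, x$n_below_5pct))
  cat(sprintf("  R_CC = %s, %s\n", format(round(x$r_cc, 3)),
              paste(names(x$omega_by_G), "=", format(round(x$omega_by_G, 3)),
                    collapse = ", ")))
  cat(sprintf("  mean PB_DC = %s, mean gamma = %s\n",
              format(round(x$mean_pb_dc, 3)), format(round(x$mean_gamma, 3))))
  if (!is.na(x$na_reason)) cat(sprintf("  NA reason: %s\n", x$na_reason))
  invisible(x)
}

#' Analyze all items of a scored dataset
#'
#' @inheritParams analyze_item
#' @return A data frame with one row per item: `item`, `n_nonsolvers`,
#'   `n_below_5pct`, `n_retained`, one `omega_<G>` column per requested group
#'   count, `r_cc`, `mean_pb_dc`, `mean_gamma`, and `na_reason`.
#' @export
analyze_items <- function(scored, config = analysis_config()) {
  rows <- lapply(seq_along(scored$items), function(j)
    analyze_item(scored, j, config))
  df <- data.frame(
    item = vapply(rows, `[[`, character(1), "item"),
    n_nonsolvers = vapply(rows, `[[`, numeric(1), "n_nonsolvers"),
    n_below_5pct = vapply(rows, `[[`, numeric(1), "n_below_5pct"),
    n_retained = vapply(rows, `[[`, numeric(1), "n_retained"),
    stringsAsFactors = FALSE)
  for (nm in names(rows[[1]]$omega_by_G))
    df[[nm]] <- vapply(rows, function(r) r$omega_by_G[[nm]], numeric(1))
  df$r_cc <- vapply(rows, `[[`, numeric(1), "r_cc")
  df$mean_pb_dc <- vapply(rows, `[[`, numeric(1), "mean_pb_dc")
  df$mean_gamma <- vapply(rows, `[[`, numeric(1), "mean_gamma")
  df$na_reason <- vapply(rows, `[[`, character(1), "na_reason")
  attr(df, "details") <- rows
  df
}

#' Per-distractor report for all items
#'
#' @inheritParams analyze_item
#' @return Long data frame: one row per item x distractor with choice counts,
#'   relative frequency, screen status, and (for retained distractors) PB_D,
#'   PB_DC, omega_D and gamma.
#' @export
distractor_report <- function(scored, config = analysis_config()) {
  out <- lapply(seq_along(scored$items), function(j) {
    a <- analyze_item(scored, j, config)
    codes <- names(a$rel_freq)
    retained <- codes %in% a$retained_distractors
    pick <- function(v) ifelse(retained, v[match(codes, names(v))], NA_real_)
    data.frame(item = a$item, distractor = codes,
               rel_freq = unname(a$rel_freq), retained = retained,
               pb_d = pick(a$pb_d), pb_dc = pick(a$pb_dc),
               omega_d = pick(a$omega_d), gamma = pick(a$gamma),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Trace tables for all items in long form
#'
#' @inheritParams analyze_item
#' @param G number of ability groups.
#' @return Long data frame: `item`, `group`, `option`, `rel_freq`.
#' @export
trace_report <- function(scored, G = 5) {
  out <- lapply(seq_along(scored$items), function(j) {
    tt <- trace_table(scored, j, G)
    data.frame(item = scored$items[j],
               group = rep(as.integer(colnames(tt)), each = nrow(tt)),
               option = rep(rownames(tt), ncol(tt)),
               rel_freq = as.vector(tt), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
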