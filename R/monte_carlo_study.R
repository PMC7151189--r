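.facet_levels <- list(
  n_persons = c(100L, 200L, 500L),
  n_items = c(10L, 20L, 50L),
  n_distractors = c(3L, 7L),
  difficulty = c("moderate", "difficult", "very_difficult"),
  discrimination = c("low", "moderate", "high"),
  nrm = c("zero", "moderate", "high", "very_high"))

#' Build the crossed simulation design
#'
#' Full cross of the six design facets (3 sample sizes x 3 test lengths x 2
#' distractor counts x 3 difficulty x 3 discrimination x 4 NRM levels = 648
#' cells), optionally filtered.
#'
#' @param filter named list of facet values to keep, e.g.
#'   `list(nrm = "zero")` for the 162 null cells.
#' @return Data frame with one row per design cell plus a `cell_id` column.
#' @export
build_design <- function(filter = NULL) {
  design <- do.call(expand.grid,
                    c(.facet_levels, list(stringsAsFactors = FALSE,
                                          KEEP.OUT.ATTRS = FALSE)))
  if (!is.null(filter)) {
    bad <- setdiff(names(filter), names(.facet_levels))
    if (length(bad) > 0)
      stop_validation("unknown design facet(s): %s", paste(bad, collapse = ", "))
    for (nm in names(filter))
      design <- design[design[[nm]] %in% filter[[nm]], , drop = FALSE]
    rownames(design) <- NULL
  }
  design$cell_id <- vapply(seq_len(nrow(design)), function(i)
    cell_id(as_cell(design[i, ])), character(1))
  design
}

as_cell <- function(row) {
  design_cell(row$n_persons, row$n_items, row$n_distractors,
              row$difficulty, row$discrimination, row$nrm)
}

# Deterministic 0-based index of a cell in the full cross; together with the
# master seed it fixes the random stream of every replicate, so cells can be
# run in any order (or in parallel) with identical output.
cell_seed_index <- function(cell) {
  ix <- c(match(cell$n_persons, .facet_levels$n_persons),
          match(cell$n_items, .facet_levels$n_items),
          match(cell$n_distractors, .facet_levels$n_distractors),
          match(cell$difficulty, .facet_levels$difficulty),
          match(cell$discrimination, .facet_levels$discrimination),
          match(cell$nrm, .facet_levels$nrm)) - 1L
  ((((ix[1] * 3L + ix[2]) * 2L + ix[3]) * 3L + ix[4]) * 3L + ix[5]) * 4L + ix[6]
}

#' Configuration of a Monte-Carlo study run
#'
#' @param reps replications per design cell.
#' @param thresholds effect-size detection cutoffs.
#' @param alpha_acceptable ceiling on the type-I detection rate (inclusive).
#' @param power_adequate floor on adequate power (inclusive).
#' @param boundary_gamma item mean gamma must exceed this under the gamma
#'   boundary condition.
#' @param boundary_pb_dc item mean PB_DC must fall below this under the PB_DC
#'   boundary condition.
#' @param master_seed integer master seed for all random streams.
#' @param measures subset of `"r_cc"`, `"omega2"`, `"omega5"`.
#' @param min_rel_freq distractor choice-frequency screen.
#' @param retain_items keep the per-item effect-size records in each cell
#'   result (needed only for re-analysis; the aggregates always include the
#'   boundary-conditioned detection rates).
#' @return A `study_config` list.
#' @export
study_config <- function(reps = 1000, thresholds = c(0.10, 0.30, 0.50),
                         alpha_acceptable = 0.05, power_adequate = 0.80,
                         boundary_gamma = 0.30, boundary_pb_dc = -0.30,
                         master_seed = 1, measures = c("r_cc", "omega2", "omega5"),
                         min_rel_freq = 0.05, retain_items = FALSE) {
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1) stop_validation("reps must be >= 1")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_validation("thresholds must lie in (0, 1)")
  measures <- match.arg(measures, c("r_cc", "omega2", "omega5"),
                        several.ok = TRUE)
  structure(list(reps = reps, thresholds = thresholds,
                 alpha_acceptable = alpha_acceptable,
                 power_adequate = power_adequate,
                 boundary_gamma = boundary_gamma,
                 boundary_pb_dc = boundary_pb_dc,
                 master_seed = as.integer(master_seed), measures = measures,
                 min_rel_freq = min_rel_freq, retain_items = retain_items),
            class = "study_config")
}

# Quantile grouping for non-negative integer scores via tabulation; same
# rule as ability_groups() (equality is property-tested), just faster.
fast_groups <- function(y, G) {
  r <- tabulate(y + 1L)
  pres <- r > 0
  vals <- which(pres) - 1L
  cum <- cumsum(r[pres]) / length(y)
  bk <- vapply(seq_len(G - 1L), function(k) vals[which(cum >= k / G)[1L]],
               numeric(1))
  list(breakpoints = bk,
       G_realized = length(unique(group_labels(vals, bk))))
}

# Lean per-item record for the study loop: only the quantities the dependent
# variables need. Mirrors analyze_item(); equality of the two paths is
# asserted in the test suite.
item_record <- function(scored, j, min_rel_freq = 0.05) {
  N <- length(scored$persons)
  corr <- scored$correct[, j]
  dcol <- scored$distractor[, j]
  m <- scored$n_distractors[[j]]
  ns <- which(!corr)
  d <- dcol[ns]
  counts <- tabulate(d, m)
  retained <- which(counts / N >= min_rel_freq)
  y_ns <- scored$total[ns]

  g2 <- g5 <- 0L
  omega2 <- omega5 <- rcc <- NA_real_
  reason2 <- reason5 <- reason_cc <- NA_character_
  if (length(ns) == 0) {
    reason2 <- reason5 <- reason_cc <- "no_nonsolvers"
  } else {
    grp2 <- fast_groups(y_ns, 2L)
    grp5 <- fast_groups(y_ns, 5L)
    g2 <- grp2$G_realized
    g5 <- grp5$G_realized
    if (length(retained) < 2) {
      reason2 <- reason5 <- reason_cc <- "insufficient_distractors"
    } else {
      in_tab <- d %in% retained
      dt <- d[in_tab]
      yt <- y_ns[in_tab]
      o2 <- omega_core(dt, yt, retained, grp2$breakpoints, 2L)
      o5 <- omega_core(dt, yt, retained, grp5$breakpoints, 5L)
      cc <- r_cc_core(dt, yt, retained)
      omega2 <- o2$value; reason2 <- o2$na_reason
      omega5 <- o5$value; reason5 <- o5$na_reason
      rcc <- cc$value; reason_cc <- cc$na_reason
    }
  }

  mg <- mpb <- NA_real_
  if (length(retained) > 0) {
    gam <- pb <- rep(NA_real_, length(retained))
    nlev <- length(scored$items) # rest scores range over 0..I-1
    y_c <- scored$total[corr]    # solvers of item j; their rest = total - 1
    n_cg <- length(y_c)
    if (n_cg > 0) {
      n_c_tab <- tabulate(y_c, nbins = nlev)
      s_c <- sum(y_c)
      ss_c <- sum(y_c * y_c)
      for (k in seq_along(retained)) {
        y_d <- y_ns[d == retained[k]]
        n_dg <- length(y_d)
        if (n_dg == 0) next
        # PB_DC within the D-choosers + solvers subgroup, from moments
        n_sub <- n_cg + n_dg
        m_sub <- (s_c + sum(y_d)) / n_sub
        v_sub <- (ss_c + sum(y_d * y_d)) / n_sub - m_sub^2
        p <- n_dg / n_sub
        if (v_sub > 0)
          pb[k] <- (mean(y_d) - m_sub) / sqrt(v_sub) * sqrt(p / (1 - p))
        gam[k] <- gamma_tab(n_c_tab, tabulate(y_d + 1L, nbins = nlev))
      }
    }
    if (any(!is.na(pb))) mpb <- mean(pb, na.rm = TRUE)
    if (any(!is.na(gam))) mg <- mean(gam, na.rm = TRUE)
  }

  list(r_cc = rcc, omega2 = omega2, omega5 = omega5,
       reason_r_cc = reason_cc, reason_omega2 = reason2,
       reason_omega5 = reason5,
       mean_gamma = mg, mean_pb_dc = mpb,
       n_below = m - length(retained), n_retained = length(retained),
       groups2 = g2, groups5 = g5, m = m)
}

#' Run all replicates of one design cell
#'
#' For each replicate an item bank is sampled, a dataset simulated, and every
#' item analyzed. Detection rates (the proportion of non-missing effect sizes
#' exceeding each threshold, with and without the gamma / PB_DC boundary
#' conditions), missing rates, the below-5% distractor rate, and the
#' ability-group realization rates are pooled over items x replicates.
#'
#' @param cell a [design_cell()] or a row of [build_design()].
#' @param config a [study_config()].
#' @return A `study_cell_result` list: `cell`, `cell_id`, `detection` (data
#'   frame measure x threshold x boundary), `missing` (per measure),
#'   `below5_rate`, `group_realization`, `n_records`, and (when
#'   `retain_items = TRUE`) the per-item `records` data frame.
#' @export
run_cell <- function(cell, config = study_config()) {
  if (!inherits(cell, "design_cell")) cell <- as_cell(as.list(cell))
  cidx <- cell_seed_index(cell)
  reps <- config$reps
  I <- cell$n_items
  n_rec <- reps * I
  num <- function() numeric(n_rec)
  rec <- list(rep = rep(seq_len(reps), each = I), item = rep(seq_len(I), reps),
              r_cc = num(), omega2 = num(), omega5 = num(),
              mean_gamma = num(), mean_pb_dc = num(),
              n_below = num(), n_retained = num(),
              groups2 = num(), groups5 = num(),
              reason_r_cc = character(n_rec), reason_omega2 = character(n_rec),
              reason_omega5 = character(n_rec))
  pos <- 0L
  for (r in seq_len(reps)) {
    bank <- sample_item_bank(cell, seed = derive_seed(config$master_seed, cidx, r, 1))
    resp <- simulate_responses(bank, cell$n_persons,
                               seed = derive_seed(config$master_seed, cidx, r, 2))
    scored <- score_responses(resp)
    for (j in seq_len(I)) {
      ir <- item_record(scored, j, config$min_rel_freq)
      pos <- pos + 1L
      rec$r_cc[pos] <- ir$r_cc
      rec$omega2[pos] <- ir$omega2
      rec$omega5[pos] <- ir$omega5
      rec$mean_gamma[pos] <- ir$mean_gamma
      rec$mean_pb_dc[pos] <- ir$mean_pb_dc
      rec$n_below[pos] <- ir$n_below
      rec$n_retained[pos] <- ir$n_retained
      rec$groups2[pos] <- ir$groups2
      rec$groups5[pos] <- ir$groups5
      rec$reason_r_cc[pos] <- ir$reason_r_cc
      rec$reason_omega2[pos] <- ir$reason_omega2
      rec$reason_omega5[pos] <- ir$reason_omega5
    }
  }
  records <- as.data.frame(rec, stringsAsFactors = FALSE)
  res <- aggregate_records(records, cell, config)
  if (config$retain_items) res$records <- records
  res
}

aggregate_records <- function(records, cell, config) {
  measures <- config$measures
  thresholds <- config$thresholds
  boundaries <- c("none", "gamma", "pb_dc")
  gamma_ok <- !is.na(records$mean_gamma) &
    records$mean_gamma > config$boundary_gamma
  pbdc_ok <- !is.na(records$mean_pb_dc) &
    records$mean_pb_dc < config$boundary_pb_dc
  det <- expand.grid(measure = measures, threshold = thresholds,
                     boundary = boundaries, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  det$rate <- NA_real_
  det$n <- NA_integer_
  for (i in seq_len(nrow(det))) {
    v <- records[[det$measure[i]]]
    ok <- !is.na(v)
    hit <- ok & v > det$threshold[i]
    hit <- switch(det$boundary[i],
                  none = hit, gamma = hit & gamma_ok, pb_dc = hit & pbdc_ok)
    det$rate[i] <- if (any(ok)) sum(hit) / sum(ok) else NA_real_
    det$n[i] <- sum(ok)
  }
  missing <- data.frame(measure = measures, stringsAsFactors = FALSE)
  missing$missing_rate <- vapply(measures, function(mm)
    mean(is.na(records[[mm]])), numeric(1))
  missing$missing_due_to_5pct_rate <- vapply(measures, function(mm)
    mean(records[[paste0("reason_", mm)]] %in% "insufficient_distractors"),
    numeric(1))
  structure(list(
    cell = cell, cell_id = cell_id(cell),
    detection = det, missing = missing,
    below5_rate = sum(records$n_below) / sum(records$n_below + records$n_retained),
    group_realization = c(g2 = sum(records$groups2) / (2 * nrow(records)),
                          g5 = sum(records$groups5) / (5 * nrow(records))),
    n_records = nrow(records)), class = "study_cell_result")
}

#' @export
print.study_cell_result <- function(x, ...) {
  cat(sprintf("study_cell_result %s: %d item records, below-5%% rate %.3f\n",
              x$cell_id, x$n_records, x$below5_rate))
  invisible(x)
}

#' Run a set of design cells
#'
#' @param design data frame from [build_design()].
#' @param config a [study_config()].
#' @param progress print one line per finished cell to stderr.
#' @return List of [run_cell()] results, named by cell id.
#' @export
run_study <- function(design, config = study_config(), progress = FALSE) {
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    t0 <- Sys.time()
    out[[i]] <- run_cell(design[i, ], config)
    if (progress)
      message(sprintf("[%d/%d] %s (%.1fs)", i, nrow(design),
                      out[[i]]$cell_id,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  names(out) <- vapply(out, `[[`, character(1), "cell_id")
  out
}

cell_facets <- function(res) {
  c <- res$cell
  data.frame(cell_id = res$cell_id, n_persons = c$n_persons,
             n_items = c$n_items, n_distractors = c$n_distractors,
             difficulty = c$difficulty, discrimination = c$discrimination,
             nrm = c$nrm, stringsAsFactors = FALSE)
}

detection_table <- function(results, boundary = "none") {
  do.call(rbind, lapply(results, function(res) {
    det <- res$detection[res$detection$boundary == boundary, , drop = FALSE]
    cbind(cell_facets(res)[rep(1L, nrow(det)), , drop = FALSE], det,
          row.names = NULL)
  }))
}

#' Summarize type-I error over the null design cells
#'
#' Over cells simulated with zero NRM discrimination, the percentage of cells
#' whose detection rate stays at or below the acceptable level, per measure
#' and threshold, plus an `"all"` row counting cell x threshold combinations
#' over the 0.30 and 0.50 thresholds.
#'
#' @param results list of [run_cell()] results, all with `nrm = "zero"`.
#' @param config the [study_config()] used.
#' @return List with `by_cell` (cell x measure x threshold rates and
#'   acceptability) and `summary` (percent acceptable per measure x
#'   threshold, including the `"all"` aggregation).
#' @export
summarize_type1 <- function(results, config = study_config()) {
  nrm <- vapply(results, function(r) r$cell$nrm, character(1))
  if (any(nrm != "zero"))
    stop_validation("summarize_type1 requires nrm = 'zero' cells only")
  by_cell <- detection_table(results, "none")
  by_cell$acceptable <- by_cell$rate <= config$alpha_acceptable
  agg <- stats::aggregate(acceptable ~ measure + threshold, by_cell,
                          function(z) 100 * mean(z))
  names(agg)[3] <- "pct_acceptable"
  main <- by_cell[by_cell$threshold %in% c(0.30, 0.50), , drop = FALSE]
  if (nrow(main) > 0) {
    all_row <- stats::aggregate(acceptable ~ measure, main,
                                function(z) 100 * mean(z))
    agg <- rbind(agg, data.frame(measure = all_row$measure, threshold = NA,
                                 pct_acceptable = all_row$acceptable))
  }
  list(by_cell = by_cell, summary = agg)
}

#' Summarize empirical power over non-null design cells
#'
#' Cells whose matching null cell (same facets apart from the NRM level) had
#' an unacceptable type-I rate for a measure x threshold combination are
#' removed first (they count as not adequate). A detection then requires the
#' effect size to exceed the threshold and, under a boundary condition, the
#' item's mean gamma to exceed `boundary_gamma` (or its mean PB_DC to fall
#' below `boundary_pb_dc`). Reported is the percentage of cells per measure x
#' threshold x NRM level whose detection rate reaches `power_adequate`.
#'
#' @param results list of [run_cell()] results with `nrm != "zero"`.
#' @param type1 result of [summarize_type1()] on the paired null run.
#' @param config the [study_config()] used.
#' @param boundary `"none"`, `"gamma"`, or `"pb_dc"`.
#' @return List with `by_cell` (power, type-I screen, adequacy per cell) and
#'   `summary` (percent adequate per measure x threshold x NRM level).
#' @export
summarize_power <- function(results, type1, config = study_config(),
                            boundary = c("none", "gamma", "pb_dc")) {
  boundary <- match.arg(boundary)
  nrm <- vapply(results, function(r) r$cell$nrm, character(1))
  if (any(nrm == "zero"))
    stop_validation("summarize_power requires nrm != 'zero' cells")
  by_cell <- detection_table(results, boundary)
  null_tab <- type1$by_cell
  key <- function(df) paste(df$n_persons, df$n_items, df$n_distractors,
                            df$difficulty, df$discrimination,
                            df$measure, df$threshold)
  by_cell$type1_acceptable <- null_tab$acceptable[match(key(by_cell), key(null_tab))]
  if (anyNA(by_cell$type1_acceptable))
    stop_validation("null run does not cover all facet combinations")
  by_cell$power <- by_cell$rate
  by_cell$adequate <- by_cell$type1_acceptable &
    !is.na(by_cell$power) & by_cell$power >= config$power_adequate
  summary <- stats::aggregate(adequate ~ measure + threshold + nrm, by_cell,
                              function(z) 100 * mean(z))
  names(summary)[4] <- "pct_adequate"
  list(by_cell = by_cell, summary = summary, boundary = boundary)
}

#' Empirical-substance summary
#'
#' Averages, with equal cell weights, the percentage of distractors below the
#' choice-frequency screen per NRM level, reports per-measure missing
#' effect-size percentages (overall and due to the screen) with their
#' across-cell maxima, and the minimum ability-group realization rates.
#'
#' @param results list of [run_cell()] results.
#' @return List with `by_cell`, `by_level` (per NRM level means and maxima
#'   for the r_cc missing rate), and `group_minima`.
#' @export
substance_summary <- function(results) {
  by_cell <- do.call(rbind, lapply(results, function(res) {
    df <- cell_facets(res)
    df$below5_pct <- 100 * res$below5_rate
    for (i in seq_len(nrow(res$missing))) {
      mm <- res$missing$measure[i]
      df[[paste0("missing_", mm, "_pct")]] <- 100 * res$missing$missing_rate[i]
      df[[paste0("missing5_", mm, "_pct")]] <-
        100 * res$missing$missing_due_to_5pct_rate[i]
    }
    df$group_real_g2 <- res$group_realization[["g2"]]
    df$group_real_g5 <- res$group_realization[["g5"]]
    df
  }))
  rownames(by_cell) <- NULL
  lev <- stats::aggregate(below5_pct ~ nrm, by_cell, mean)
  names(lev)[2] <- "mean_below5_pct"
  if ("missing_r_cc_pct" %in% names(by_cell)) {
    mx <- stats::aggregate(missing_r_cc_pct ~ nrm, by_cell, max)
    lev$max_missing_pct <- mx$missing_r_cc_pct[match(lev$nrm, mx$nrm)]
    mx5 <- stats::aggregate(missing5_r_cc_pct ~ nrm, by_cell, max)
    lev$max_missing5_pct <- mx5$missing5_r_cc_pct[match(lev$nrm, mx5$nrm)]
  }
  list(by_cell = by_cell, by_level = lev,
       group_minima = c(g2 = min(by_cell$group_real_g2),
                        g5 = min(by_cell$group_real_g5)))
}
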