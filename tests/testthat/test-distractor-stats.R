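test_that("the choice-frequency screen uses an inclusive boundary", {
  # 100 persons; distractor "1" chosen 5 times (exactly 5%), "2" chosen 4
  # times, "3" chosen 91 times
  d1 <- c(rep("1", 5), rep("2", 4), rep("3", 91))
  sc <- make_item1_fixture(d1, extra_correct = rep(1, 100))
  scr <- screen_distractors(sc, 1)
  expect_true("1" %in% scr$retained_codes)
  expect_false("2" %in% scr$retained_codes)
  expect_equal(scr$n_below, 1L)
  expect_equal(scr$counts, c(5, 4, 91))
})

test_that("omega and R_CC hit their boundary values on hand-built tables", {
  # 10 non-solvers choosing d1 with low scores, 10 choosing d2 with high
  # scores -> 2x2 table [[10,0],[0,10]]: chi2 = 20, n = 20, omega = 1; zero
  # within-group score variance -> R_CC = 1
  sc <- make_item1_fixture(c(rep("1", 10), rep("2", 10)),
                           extra_correct = c(rep(0, 10), rep(2, 10)))
  expect_equal(as.numeric(cohen_omega_g(sc, 1, 2)), 1)
  expect_equal(as.numeric(canonical_correlation(sc, 1)), 1)

  # proportional columns: each score level has the same distractor mix
  sc0 <- make_item1_fixture(rep(c("1", "2"), 10),
                            extra_correct = rep(c(0, 0, 2, 2), 5))
  expect_equal(as.numeric(cohen_omega_g(sc0, 1, 2)), 0)
  expect_equal(as.numeric(canonical_correlation(sc0, 1)), 0, tolerance = 1e-12)
})

test_that("omega_G equals sqrt(chi2/n) with chi-squared recomputed independently", {
  for (s in 1:30) {
    sc <- sim_scored(n = 80, distractors = if (s %% 2) 3 else 7, seed = s)
    for (j in c(1, 5)) {
      for (G in c(2, 5)) {
        got <- cohen_omega_g(sc, j, G)
        scr <- screen_distractors(sc, j)
        ns <- nonsolver_view(sc, j)
        if (length(scr$retained) < 2 || length(ns$total) == 0) {
          expect_true(is.na(got))
          next
        }
        grp <- ability_groups(ns$total, G)
        keep <- ns$distractor %in% scr$retained
        tab <- table(ns$distractor[keep], grp$labels[keep])
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (nrow(tab) < 2 || ncol(tab) < 2) {
          expect_true(is.na(got))
        } else {
          chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
          expect_equal(as.numeric(got), sqrt(as.numeric(chi2) / sum(tab)),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("R_CC equals the correlation ratio eta and ignores the dropped indicator", {
  n_checked <- 0
  for (s in 1:30) {
    sc <- sim_scored(n = 70, distractors = if (s %% 2) 3 else 7,
                     nrm = c("zero", "moderate", "high")[s %% 3 + 1], seed = s + 100)
    for (j in c(2, 8)) {
      got <- canonical_correlation(sc, j)
      scr <- screen_distractors(sc, j)
      ns <- nonsolver_view(sc, j)
      keep <- ns$distractor %in% scr$retained
      y <- ns$total[keep]
      if (is.na(got)) next
      g <- factor(ns$distractor[keep])
      sst <- sum((y - mean(y))^2)
      ssw <- sum(unlist(tapply(y, g, function(z) sum((z - mean(z))^2))))
      expect_equal(as.numeric(got), sqrt(1 - ssw / sst), tolerance = 1e-10)
      # drop-one coding invariance
      for (dr in seq_along(scr$retained)) {
        alt <- distractr:::r_cc_detail(sc, j, 0.05, drop = dr)$value
        expect_equal(alt, as.numeric(got), tolerance = 1e-10)
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 30)
})

test_that("point-biserials equal Pearson correlations of choice indicators", {
  for (s in 1:25) {
    sc <- sim_scored(n = 60, distractors = 3, seed = s + 300)
    for (j in c(1, 6)) {
      m <- sc$n_distractors[[j]]
      for (v in seq_len(m)) {
        ind <- !is.na(sc$distractor[, j]) & sc$distractor[, j] == v
        pbd <- point_biserial_d(sc, j, v)
        if (!is.na(pbd))
          expect_equal(pbd, suppressWarnings(stats::cor(as.numeric(ind), sc$total)),
                       tolerance = 1e-12)
        sub <- ind | sc$correct[, j]
        pbdc <- point_biserial_dc(sc, j, v)
        if (!is.na(pbdc) && stats::sd(ind[sub]) > 0)
          expect_equal(pbdc,
                       stats::cor(as.numeric(ind[sub]), sc$total[sub]),
                       tolerance = 1e-12)
      }
    }
  }
})

test_that("point-biserial degenerate cases return NA", {
  sc <- make_item1_fixture(rep("1", 10), extra_correct = rep(1, 10))
  # nobody solved item 1 -> PB_DC has no solver group
  expect_true(is.na(point_biserial_dc(sc, 1, 1)))
  # distractor 2 never chosen -> P_D = 0
  expect_true(is.na(point_biserial_d(sc, 1, 2)))
})

test_that("per-distractor omega_D matches a hand goodness-of-fit computation", {
  # two score groups; D chosen 10 times in group 1, never in group 2:
  # chi2 = (10-5)^2/5 + (0-5)^2/5 = 10, omega_D = sqrt(10/10) = 1
  sc <- make_item1_fixture(c(rep("1", 10), rep("0", 10)),
                           extra_correct = c(rep(0, 10), rep(3, 10)))
  expect_equal(haladyna_omega_d(sc, 1, 1, G = 2), 1)

  # uniform choice counts across groups -> 0
  sc_u <- make_item1_fixture(rep("1", 10), extra_correct = rep(0:4, each = 2))
  expect_equal(haladyna_omega_d(sc_u, 1, 1, G = 5), 0)

  # random-data oracle
  for (s in 1:15) {
    sc_r <- sim_scored(n = 80, seed = s + 500)
    grp <- ability_groups(sc_r$total, 5)
    for (v in 1:3) {
      got <- haladyna_omega_d(sc_r, 1, v, G = 5)
      chose <- !is.na(sc_r$distractor[, 1]) & sc_r$distractor[, 1] == v
      n_d <- sum(chose)
      if (n_d == 0 || grp$G_realized < 2) {
        expect_true(is.na(got))
        next
      }
      counts <- table(factor(grp$labels[chose], levels = sort(unique(grp$labels))))
      chi2 <- suppressWarnings(stats::chisq.test(as.numeric(counts))$statistic)
      expect_equal(got, sqrt(as.numeric(chi2) / n_d), tolerance = 1e-10)
    }
  }
})

test_that("gamma is 1 for rising and -1 for falling solving probabilities", {
  # rest-score levels 0,1,2 with p(correct) = 0, .5, 1: strictly rising
  sc <- make_item1_fixture(c("1", "1", "0", "1", "0"),
                           extra_correct = c(0, 0, 1, 1, 2))
  expect_equal(goodman_kruskal_gamma(sc, 1, 1), 1)
  # reverse the pattern: p(correct) falls with rest score
  sc2 <- make_item1_fixture(c("0", "0", "1", "0", "1"),
                            extra_correct = c(0, 0, 1, 1, 2))
  expect_equal(goodman_kruskal_gamma(sc2, 1, 1), -1)
  # single score level -> NA
  sc3 <- make_item1_fixture(c("0", "1"), extra_correct = c(1, 1))
  expect_true(is.na(goodman_kruskal_gamma(sc3, 1, 1)))
})

test_that("weighted gamma matches the classic table formula", {
  for (s in 1:10) {
    sc <- sim_scored(n = 80, seed = s + 700)
    v <- 1
    got <- goodman_kruskal_gamma(sc, 1, v, weighted = TRUE)
    chose <- !is.na(sc$distractor[, 1]) & sc$distractor[, 1] == v
    sub <- chose | sc$correct[, 1]
    if (!any(chose) || !any(sc$correct[, 1])) next
    rest <- sc$rest[sub, 1]
    corr <- sc$correct[sub, 1]
    lev <- sort(unique(rest))
    conc <- disc <- 0
    for (a in seq_along(lev)) for (b in seq_along(lev)) {
      if (lev[b] <= lev[a]) next
      conc <- conc + sum(!corr & rest == lev[a]) * sum(corr & rest == lev[b])
      disc <- disc + sum(corr & rest == lev[a]) * sum(!corr & rest == lev[b])
    }
    if (conc + disc == 0) expect_true(is.na(got))
    else expect_equal(got, (conc - disc) / (conc + disc), tolerance = 1e-12)
  }
})

test_that("effect sizes respect their theoretical ranges on random data", {
  for (s in 1:20) {
    sc <- sim_scored(n = 50, distractors = if (s %% 2) 3 else 7,
                     nrm = c("zero", "very_high")[s %% 2 + 1], seed = s + 900)
    for (j in seq_along(sc$items)) {
      o2 <- cohen_omega_g(sc, j, 2); o5 <- cohen_omega_g(sc, j, 5)
      rc <- canonical_correlation(sc, j)
      if (!is.na(o2)) expect_gte(as.numeric(o2), 0)
      if (!is.na(o5)) expect_gte(as.numeric(o5), 0)
      if (!is.na(rc)) {
        expect_gte(as.numeric(rc), 0)
        expect_lte(as.numeric(rc), 1)
      }
      for (v in seq_len(sc$n_distractors[[j]])) {
        pb <- point_biserial_d(sc, j, v)
        gm <- goodman_kruskal_gamma(sc, j, v)
        if (!is.na(pb)) expect_true(pb >= -1 && pb <= 1)
        if (!is.na(gm)) expect_true(gm >= -1 && gm <= 1)
      }
    }
  }
})

test_that("trace tables are proper conditional distributions", {
  sc <- sim_scored(n = 200, seed = 77)
  tt <- trace_table(sc, 3, G = 5)
  expect_true(all(abs(colSums(tt) - 1) < 1e-12))
  expect_equal(nrow(tt), 1 + sc$n_distractors[[3]])
  expect_equal(sum(attr(tt, "group_sizes")), 200)
})

test_that("at large N the correct-option trace line rises with ability group", {
  sc <- score_responses(example_item_data(1, 10000, seed = 2))
  tt <- trace_table(sc, 1, G = 5)
  expect_true(all(diff(tt["0", ]) > 0))
  # zero NRM discrimination: no group x distractor interaction in the
  # distractor sub-table
  ns_tab <- tt[-1, ] * rep(attr(tt, "group_sizes"), each = nrow(tt) - 1)
  chi2 <- suppressWarnings(stats::chisq.test(ns_tab, correct = FALSE))$statistic
  expect_lt(as.numeric(chi2), stats::qchisq(0.999, df = 8))
})
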