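#' The two-parameter nested logit (2PNL) response model
#'
#' Responses to a multiple-choice item are generated in two stages. First a
#' 2PL logistic model decides whether a person of ability theta solves the
#' item: P(solve) = 1 / (1 + exp(-(beta + alpha * theta))), with easiness
#' intercept beta and discrimination slope alpha. Second, given non-solution,
#' the distractor choice follows Bock's nominal response model: distractor v
#' receives conditional probability softmax(zeta_v + lambda_v * theta) over
#' the m distractors.
#'
#' @param theta ability value(s).
#' @param alpha 2PL discrimination slope.
#' @param beta 2PL easiness intercept (larger = easier).
#' @return `p_correct`: solving probability, same length as `theta`.
#' @export
p_correct <- function(theta, alpha, beta) {
  stats::plogis(beta + alpha * theta)
}

#' @rdname p_correct
#' @param zeta numeric vector of NRM intercepts, one per distractor.
#' @param lambda numeric vector of NRM slopes (distractor discriminations),
#'   same length as `zeta`.
#' @return `p_options`: for scalar `theta` a probability vector over
#'   (correct option, distractor 1..m); for vector `theta` a matrix with one
#'   row per ability value. Rows always sum to 1.
#' @export
p_options <- function(theta, alpha, beta, zeta, lambda) {
  if (length(zeta) != length(lambda) || length(zeta) < 1)
    stop_validation("`zeta` and `lambda` must be equal-length, non-empty vectors")
  pc <- p_correct(theta, alpha, beta)
  # softmax over distractors, centred for numerical stability
  z <- outer(theta, lambda) + rep(zeta, each = length(theta))
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  w <- e / rowSums(e)
  out <- cbind(correct = pc, (1 - pc) * w)
  colnames(out) <- c("correct", paste0("d", seq_along(zeta)))
  if (length(theta) == 1L) out[1L, ] else out
}

# ---------------------------------------------------------------------------
# Design cells and parameter sampling

.beta_ranges <- list(moderate = c(-0.15, 0.15),
                     difficult = c(-1.15, -0.85),
                     very_difficult = c(-2.25, -1.85))
.alpha_ranges <- list(low = c(0.25, 0.55),
                      moderate = c(0.85, 1.15),
                      high = c(1.60, 1.90))
# NRM slope grids: symmetric ladders around zero whose step size defines the
# level of distractor discrimination (0 / 0.40 / 1.00 / 1.75).
.lambda_steps <- c(zero = 0, moderate = 0.40, high = 1.00, very_high = 1.75)

#' NRM slope grid for a discrimination level
#'
#' The simulation design uses fixed ladders of distractor slopes, symmetric
#' around zero with step sizes 0, 0.40, 1.00 and 1.75 for the levels zero,
#' moderate, high and very_high (so e.g. high with 7 distractors gives
#' -3, -2, -1, 0, 1, 2, 3).
#'
#' @param nrm_level one of `"zero"`, `"moderate"`, `"high"`, `"very_high"`.
#' @param n_distractors 3 or 7.
#' @return Numeric vector of `n_distractors` slopes in ascending order.
#' @export
nrm_lambda <- function(nrm_level, n_distractors) {
  nrm_level <- match.arg(nrm_level, names(.lambda_steps))
  if (!n_distractors %in% c(3L, 7L))
    stop_validation("n_distractors must be 3 or 7")
  step <- .lambda_steps[[nrm_level]]
  half <- (n_distractors - 1) / 2
  step * seq(-half, half)
}

#' Define a simulation design cell
#'
#' One cell of the crossed simulation design: sample size, test length,
#' distractor count, 2PL difficulty and discrimination levels, and NRM
#' distractor-discrimination level.
#'
#' @param n_persons 100, 200, or 500.
#' @param n_items 10, 20, or 50.
#' @param n_distractors 3 or 7.
#' @param difficulty `"moderate"`, `"difficult"`, or `"very_difficult"`.
#' @param discrimination `"low"`, `"moderate"`, or `"high"`.
#' @param nrm `"zero"`, `"moderate"`, `"high"`, or `"very_high"`.
#' @return A `design_cell` list.
#' @export
design_cell <- function(n_persons, n_items, n_distractors,
                        difficulty, discrimination, nrm) {
  n_persons <- as.integer(n_persons)
  n_items <- as.integer(n_items)
  n_distractors <- as.integer(n_distractors)
  if (!n_persons %in% c(100L, 200L, 500L) || !n_items %in% c(10L, 20L, 50L) ||
      !n_distractors %in% c(3L, 7L))
    stop_validation("invalid design-cell size levels")
  difficulty <- match.arg(difficulty, names(.beta_ranges))
  discrimination <- match.arg(discrimination, names(.alpha_ranges))
  nrm <- match.arg(nrm, names(.lambda_steps))
  structure(list(n_persons = n_persons, n_items = n_items,
                 n_distractors = n_distractors, difficulty = difficulty,
                 discrimination = discrimination, nrm = nrm),
            class = "design_cell")
}

#' @export
print.design_cell <- function(x, ...) {
  cat(sprintf("design_cell: N=%d, I=%d, D=%d, difficulty=%s, discrimination=%s, nrm=%s\n",
              x$n_persons, x$n_items, x$n_distractors, x$difficulty,
              x$discrimination, x$nrm))
  invisible(x)
}

cell_id <- function(cell) {
  sprintf("N%d_I%d_D%d_%s_%s_%s", cell$n_persons, cell$n_items,
          cell$n_distractors, cell$difficulty, cell$discrimination, cell$nrm)
}

#' Sample an item bank for a design cell
#'
#' Difficulty intercepts and discrimination slopes are drawn uniformly from
#' the cell's level ranges (moderate beta in U(-0.15, 0.15), difficult in
#' U(-1.15, -0.85), very difficult in U(-2.25, -1.85); low alpha in
#' U(0.25, 0.55), moderate in U(0.85, 1.15), high in U(1.60, 1.90)). NRM
#' intercepts zeta are i.i.d. U(-1, 1) per distractor; NRM slopes are the
#' fixed [nrm_lambda()] grid of the cell's level, assigned to distractor
#' slots in ascending order.
#'
#' @param cell a [design_cell()].
#' @param seed optional integer seed (local to this call).
#' @return An `item_bank` with per-item `alpha`, `beta`, a `zeta` matrix
#'   (items x distractors), the shared `lambda` vector, and provenance.
#' @export
sample_item_bank <- function(cell, seed = NULL) {
  with_seed(seed, {
    I <- cell$n_items
    m <- cell$n_distractors
    beta <- stats::runif(I, .beta_ranges[[cell$difficulty]][1],
                         .beta_ranges[[cell$difficulty]][2])
    alpha <- stats::runif(I, .alpha_ranges[[cell$discrimination]][1],
                          .alpha_ranges[[cell$discrimination]][2])
    zeta <- matrix(stats::runif(I * m, -1, 1), I, m)
    items <- sprintf("i%02d", seq_len(I))
    rownames(zeta) <- items
    structure(list(items = items, alpha = stats::setNames(alpha, items),
                   beta = stats::setNames(beta, items), zeta = zeta,
                   lambda = nrm_lambda(cell$nrm, m),
                   cell = cell, seed = seed),
              class = "item_bank")
  })
}

#' @export
print.item_bank <- function(x, ...) {
  step <- if (length(x$lambda) > 1) diff(x$lambda)[1] else 0
  cat(sprintf("item_bank: %d items, %d distractors, lambda step %s\n",
              length(x$items), length(x$lambda), format(step)))
  invisible(x)
}

#' Write / read an item bank as CSV
#'
#' Columns: item, alpha, beta, zeta_1..m, lambda_1..m.
#'
#' @param bank an `item_bank`.
#' @param path CSV path.
#' @return `write_item_bank`: invisibly the path; `read_item_bank`: an
#'   `item_bank` (with `cell` provenance unset).
#' @export
write_item_bank <- function(bank, path) {
  m <- length(bank$lambda)
  df <- data.frame(item = bank$items, alpha = unname(bank$alpha),
                   beta = unname(bank$beta))
  zet <- as.data.frame(bank$zeta)
  names(zet) <- paste0("zeta_", seq_len(m))
  lam <- as.data.frame(matrix(bank$lambda, length(bank$items), m, byrow = TRUE))
  names(lam) <- paste0("lambda_", seq_len(m))
  utils::write.csv(cbind(df, zet, lam), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.csv(path)
  zcols <- grep("^zeta_", names(df))
  lcols <- grep("^lambda_", names(df))
  if (length(zcols) == 0 || length(zcols) != length(lcols))
    stop_validation("item bank CSV needs matching zeta_*/lambda_* columns")
  lambda <- as.numeric(df[1, lcols])
  items <- as.character(df$item)
  zeta <- as.matrix(df[, zcols, drop = FALSE])
  rownames(zeta) <- items
  structure(list(items = items,
                 alpha = stats::setNames(df$alpha, items),
                 beta = stats::setNames(df$beta, items),
                 zeta = zeta, lambda = lambda, cell = NULL, seed = NULL),
            class = "item_bank")
}

#' Simulate a response dataset from an item bank
#'
#' Each person draws an ability theta from the standard normal distribution;
#' each response is drawn from the 2PNL option probabilities of
#' [p_options()]. Option codes follow the convention correct = "0",
#' distractors = "1".."m" in slope order.
#'
#' @param bank an `item_bank` from [sample_item_bank()] or [read_item_bank()].
#' @param n_persons number of persons (default: the bank's design cell).
#' @param seed optional integer seed (local to this call).
#' @param theta optional fixed ability vector overriding the normal draw.
#' @return A [response_matrix()] with the latent `theta` vector attached.
#' @export
simulate_responses <- function(bank, n_persons = NULL, seed = NULL, theta = NULL) {
  if (is.null(n_persons))
    n_persons <- if (!is.null(bank$cell)) bank$cell$n_persons else
      stop_validation("n_persons required when the bank has no design cell")
  n_persons <- as.integer(n_persons)
  with_seed(seed, {
    I <- length(bank$items)
    m <- length(bank$lambda)
    if (is.null(theta)) theta <- stats::rnorm(n_persons)
    data <- matrix(0L, n_persons, I)
    if (n_persons > 0) {
      for (j in seq_len(I)) {
        pc <- p_correct(theta, bank$alpha[[j]], bank$beta[[j]])
        solved <- stats::runif(n_persons) < pc
        ns <- which(!solved)
        col <- integer(n_persons)
        if (length(ns) > 0) {
          z <- outer(theta[ns], bank$lambda) +
            rep(bank$zeta[j, ], each = length(ns))
          mx <- z[, 1L]
          for (v in seq_len(m - 1L)) mx <- pmax(mx, z[, v + 1L])
          e <- exp(z - mx)
          tot <- rowSums(e)
          u <- stats::runif(length(ns)) * tot
          pick <- rep(1L, length(ns))
          acc <- e[, 1L]
          for (v in seq_len(m - 1L)) {
            pick <- pick + (u > acc)
            acc <- acc + e[, v + 1L]
          }
          col[ns] <- pick
        }
        data[, j] <- col
      }
    }
    dimnames(data) <- list(if (n_persons > 0) sprintf("p%04d", seq_len(n_persons)) else NULL,
                           bank$items)
    key <- stats::setNames(rep("0", I), bank$items)
    distr <- stats::setNames(rep(list(as.character(seq_len(m))), I), bank$items)
    new_response_matrix(data, key, distr, theta = theta)
  })
}

#' Generate the worked-example datasets
#'
#' Two large illustration datasets from the same population model except for
#' the NRM distractor discrimination: 10 difficult items with moderate 2PL
#' discrimination and 3 distractors, N = 10,000 persons. The two banks share
#' the same 2PL and intercept draws; example 1 fixes all distractor slopes at
#' zero while example 2 uses the high level. The first item of each bank is
#' the illustration item.
#'
#' @param which 1 (zero NRM) or 2 (discriminating distractors).
#' @param n_persons sample size, default 10000.
#' @param seed integer seed.
#' @param nrm_level override for the example-2 NRM level (default "high").
#' @return A [response_matrix()] with theta attached.
#' @export
example_item_data <- function(which = 1, n_persons = 10000, seed = 1,
                              nrm_level = c("high", "moderate", "very_high")) {
  nrm_level <- match.arg(nrm_level)
  level <- if (which == 1) "zero" else nrm_level
  cell <- design_cell(500, 10, 3, "difficult", "moderate", level)
  cell$n_persons <- as.integer(n_persons) # illustration size, outside grid
  bank <- sample_item_bank(cell, seed = derive_seed(seed, 11))
  simulate_responses(bank, n_persons, seed = derive_seed(seed, 12, which))
}
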