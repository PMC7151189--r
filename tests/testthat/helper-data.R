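# Small builders used across the suite.

# Response matrix from a character matrix of codes; default key marks "0"
# correct for every item.
make_rm <- function(codes, key = NULL, universe = NULL) {
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("i", seq_len(ncol(codes)))
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("p", seq_len(nrow(codes)))
  if (is.null(key))
    key <- stats::setNames(rep("0", ncol(codes)), colnames(codes))
  response_matrix(codes, key, universe)
}

make_scored <- function(codes, key = NULL, universe = NULL) {
  score_responses(make_rm(codes, key, universe))
}

# A quick simulated scored dataset.
sim_scored <- function(n = 60, items = 10, distractors = 3,
                       difficulty = "difficult", discrimination = "moderate",
                       nrm = "high", seed = 1) {
  cell <- design_cell(100, items, distractors, difficulty, discrimination, nrm)
  bank <- sample_item_bank(cell, seed = seed)
  score_responses(simulate_responses(bank, n, seed = seed + 1000))
}

# Hand fixture: item 1 analyzed, the remaining items only supply score
# spread. `d1` gives item-1 responses per person ("0" = correct, "1".."3" a
# distractor), `extra_correct` the number of other items each person solves.
make_item1_fixture <- function(d1, extra_correct) {
  stopifnot(length(d1) == length(extra_correct))
  n <- length(d1)
  n_extra <- max(3, max(extra_correct))
  codes <- matrix("1", n, 1 + n_extra)
  codes[, 1] <- d1
  for (p in seq_len(n)) if (extra_correct[p] > 0)
    codes[p, 1 + seq_len(extra_correct[p])] <- "0"
  uni <- rep(list(c("0", "1", "2", "3")), ncol(codes))
  names(uni) <- paste0("i", seq_len(ncol(codes)))
  make_scored(codes, universe = uni)
}
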