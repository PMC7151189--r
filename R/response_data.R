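#' Multiple-choice response matrices
#'
#' A `response_matrix` holds a persons-by-items table of categorical option
#' codes together with a scoring key and, per item, the set of legal option
#' codes (one correct option plus the distractors). Internally the responses
#' are stored as integers (0 = correct option, 1..m = distractor in universe
#' order); the character codes are recovered on write.
#'
#' @param codes character matrix (persons x items) of option codes, with
#'   dimnames giving person and item identifiers.
#' @param key named character vector mapping every item to its correct code.
#' @param universe optional named list mapping items to their full code
#'   universe (the correct code plus distractors). When omitted, the universe
#'   of an item is the set of observed codes plus the key code, with
#'   distractors ordered by sorted code.
#' @param theta optional numeric vector of latent abilities (diagnostics from
#'   the simulator); never used by any statistic.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(codes, key, universe = NULL, theta = NULL) {
  if (!is.matrix(codes) || !is.character(codes))
    stop_validation("`codes` must be a character matrix")
  persons <- rownames(codes)
  items <- colnames(codes)
  if (is.null(items)) stop_validation("`codes` must have item column names")
  if (is.null(persons)) persons <- as.character(seq_len(nrow(codes)))
  if (anyDuplicated(persons)) stop_validation("duplicate person identifier")
  if (anyDuplicated(items)) stop_validation("duplicate item identifier")
  if (!all(items %in% names(key)))
    stop_validation("scoring key missing for item(s): %s",
                    paste(setdiff(items, names(key)), collapse = ", "))
  extra <- setdiff(names(key), items)
  if (length(extra) > 0)
    stop_validation("unknown item in key: %s", paste(extra, collapse = ", "))
  key <- key[items]
  if (anyNA(codes) || any(codes == ""))
    stop_validation("missing response")

  distractors <- vector("list", length(items))
  names(distractors) <- items
  data <- matrix(0L, nrow(codes), ncol(codes), dimnames = list(persons, items))
  for (j in seq_along(items)) {
    it <- items[j]
    if (is.null(universe)) {
      uni <- union(key[[it]], sort(unique(codes[, j])))
    } else {
      uni <- universe[[it]]
      if (is.null(uni)) stop_validation("no option universe declared for item '%s'", it)
    }
    if (!key[[it]] %in% uni)
      stop_validation("key code '%s' of item '%s' not in its option universe", key[[it]], it)
    dis <- setdiff(uni, key[[it]])
    if (length(dis) < 1)
      stop_validation("item '%s' has no distractors in its option universe", it)
    idx <- match(codes[, j], c(key[[it]], dis)) - 1L
    if (anyNA(idx)) {
      bad <- unique(codes[is.na(idx), j])
      stop_validation("code(s) %s of item '%s' absent from declared universe",
                      paste(sQuote(bad), collapse = ", "), it)
    }
    data[, j] <- idx
    distractors[[it]] <- dis
  }
  structure(list(data = data, key = key, distractors = distractors,
                 persons = persons, items = items, theta = theta),
            class = "response_matrix")
}

# Internal fast constructor used by the simulator: `data` is already the
# integer coding (0 = correct, 1..m = distractor slot).
new_response_matrix <- function(data, key, distractors, theta = NULL) {
  structure(list(data = data, key = key, distractors = distractors,
                 persons = rownames(data), items = colnames(data),
                 theta = theta),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d persons x %d items\n",
              length(x$persons), length(x$items)))
  m <- vapply(x$distractors, length, integer(1))
  cat(sprintf("  distractors per item: %s\n",
              paste(unique(range(m)), collapse = "-")))
  if (!is.null(x$theta)) cat("  latent theta vector attached\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$data)

#' Recover the character option codes of a response matrix
#'
#' @param x a `response_matrix`.
#' @return Character matrix of option codes (persons x items).
#' @export
response_codes <- function(x) {
  out <- matrix("", nrow(x$data), ncol(x$data), dimnames = dimnames(x$data))
  for (j in seq_along(x$items)) {
    uni <- c(x$key[[j]], x$distractors[[j]])
    out[, j] <- uni[x$data[, j] + 1L]
  }
  out
}

#' Per-item option universes
#'
#' @param x a `response_matrix`.
#' @return Named list: for each item the correct code followed by the
#'   distractor codes in internal order.
#' @export
option_universe <- function(x) {
  stats::setNames(lapply(seq_along(x$items), function(j)
    c(x$key[[j]], x$distractors[[j]])), x$items)
}

#' Read a response matrix and scoring key from CSV files
#'
#' The response file has a header row naming the items, with the first column
#' holding person identifiers; the key file has one row per item with columns
#' `item` and `correct`. An optional universe file (columns `item`, `code`)
#' declares the legal codes explicitly; otherwise the universe of an item is
#' the observed codes plus the key code.
#'
#' @param path response CSV.
#' @param key_path key CSV.
#' @param universe_path optional universe CSV.
#' @param missing policy for empty cells: `"error"` (default) rejects the
#'   file; `"drop"` removes incomplete persons and reports the count.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, key_path, universe_path = NULL,
                           missing = c("error", "drop")) {
  missing <- match.arg(missing)
  for (p in c(path, key_path, universe_path))
    if (!file.exists(p)) stop_io("file not found: %s", p)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop_validation("response file needs a person column and at least one item")
  persons <- raw[[1]]
  if (anyDuplicated(persons)) stop_validation("duplicate person identifier")
  codes <- as.matrix(raw[, -1, drop = FALSE])
  rownames(codes) <- persons
  miss <- is.na(codes) | codes == ""
  if (any(miss)) {
    if (missing == "error") stop_validation("missing response")
    keep <- rowSums(miss) == 0
    message(sprintf("read_responses: dropped %d person(s) with missing cells",
                    sum(!keep)))
    codes <- codes[keep, , drop = FALSE]
  }
  keydf <- utils::read.csv(key_path, colClasses = "character")
  if (!all(c("item", "correct") %in% names(keydf)))
    stop_validation("key file must have columns 'item' and 'correct'")
  key <- stats::setNames(keydf$correct, keydf$item)
  universe <- NULL
  if (!is.null(universe_path)) {
    unidf <- utils::read.csv(universe_path, colClasses = "character")
    if (!all(c("item", "code") %in% names(unidf)))
      stop_validation("universe file must have columns 'item' and 'code'")
    universe <- split(unidf$code, factor(unidf$item, levels = unique(unidf$item)))
  }
  response_matrix(codes, key, universe)
}

#' Write a response matrix (and optionally its key/universe) to CSV
#'
#' @param x a `response_matrix`.
#' @param path response CSV to write.
#' @param key_path optional key CSV to write.
#' @param universe_path optional universe CSV to write.
#' @return Invisibly, `x`.
#' @export
write_responses <- function(x, path, key_path = NULL, universe_path = NULL) {
  codes <- response_codes(x)
  df <- data.frame(person = x$persons, codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(key_path))
    utils::write.csv(data.frame(item = x$items, correct = unname(x$key)),
                     key_path, row.names = FALSE, quote = FALSE)
  if (!is.null(universe_path)) {
    uni <- option_universe(x)
    utils::write.csv(data.frame(item = rep(x$items, lengths(uni)),
                                code = unlist(uni, use.names = FALSE)),
                     universe_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}

#' Score a response matrix
#'
#' Derives binary correctness, the chosen distractor (defined only where the
#' item was not solved), raw number-correct total scores, and rest scores
#' (total minus the item's own correctness).
#'
#' @param x a [response_matrix()].
#' @return An object of class `scored_data` with elements `correct` (logical
#'   persons x items), `distractor` (integer slot 1..m, `NA` where correct),
#'   `total`, `rest` (persons x items), plus the key and distractor code maps.
#' @export
score_responses <- function(x) {
  if (!inherits(x, "response_matrix")) stop_validation("`x` must be a response_matrix")
  correct <- x$data == 0L
  distractor <- x$data
  distractor[correct] <- NA_integer_
  total <- as.integer(rowSums(correct))
  rest <- total - correct
  storage.mode(rest) <- "integer"
  structure(list(correct = correct, distractor = distractor,
                 total = total, rest = rest,
                 persons = x$persons, items = x$items,
                 key = x$key, distractor_codes = x$distractors,
                 n_distractors = vapply(x$distractors, length, integer(1)),
                 theta = x$theta),
            class = "scored_data")
}

#' @export
print.scored_data <- function(x, ...) {
  cat(sprintf("scored_data: %d persons x %d items; mean total score %.2f\n",
              length(x$persons), length(x$items), mean(x$total)))
  invisible(x)
}

# Resolve an item given by name or index to its column index.
item_index <- function(scored, item) {
  if (is.character(item)) {
    j <- match(item, scored$items)
    if (is.na(j)) stop_validation("unknown item '%s'", item)
  } else {
    j <- as.integer(item)
    if (is.na(j) || j < 1 || j > length(scored$items))
      stop_validation("item index out of range: %s", item)
  }
  j
}

#' Restrict scores to the non-solvers of one item
#'
#' Returns, for all persons who did not solve the item, the chosen distractor
#' together with their total and rest scores, in stable person order.
#'
#' @param scored a [score_responses()] result.
#' @param item item name or index.
#' @return A list with `persons`, `distractor` (integer slot), `code`
#'   (character distractor code), `total`, and `rest`.
#' @export
nonsolver_view <- function(scored, item) {
  j <- item_index(scored, item)
  ns <- which(!scored$correct[, j])
  d <- scored$distractor[ns, j]
  list(persons = scored$persons[ns],
       distractor = d,
       code = scored$distractor_codes[[j]][d],
       total = scored$total[ns],
       rest = scored$rest[ns, j])
}
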