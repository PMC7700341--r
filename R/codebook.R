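#' Construct an instrument item definition
#'
#' @param id Unique item identifier.
#' @param construct Behavioural construct label (e.g. `"Vegetables"`,
#'   `"Sleep"`).
#' @param prompt Item text shown to the respondent.
#' @param option_scores Named numeric vector mapping response-option labels to
#'   scores, in healthfulness order. Scores must lie on the half-point grid in
#'   `[1, 5]` and be non-decreasing; the healthiest option need not reach 5.
#' @return An object of class `item_def`.
#' @export
item_def <- function(id, construct, prompt, option_scores) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(construct), length(construct) == 1L, nzchar(construct))
  if (is.null(names(option_scores)) || any(!nzchar(names(option_scores))))
    stop("option_scores must be a named vector (item ", id, ")")
  if (length(option_scores) < 2L)
    stop("item ", id, " must have at least 2 response options")
  option_scores <- stats::setNames(as.numeric(option_scores),
                                   names(option_scores))
  check_score_grid(option_scores, paste0("item ", id))
  if (any(diff(unname(option_scores)) < 0))
    stop("item ", id, ": option scores must be non-decreasing in healthfulness order")
  structure(list(id = id, construct = construct, prompt = prompt,
                 option_scores = option_scores),
            class = "item_def")
}

# scores must sit on the 0.5 grid within [1, 5]
check_score_grid <- function(scores, what) {
  if (any(!is.finite(scores)) || any(scores < 1) || any(scores > 5))
    stop(what, ": scores must lie in [1, 5]")
  off <- abs(scores * 2 - round(scores * 2)) > 1e-8
  if (any(off)) stop(what, ": scores must lie on the 0.5 grid")
  invisible(scores)
}

#' Assemble and validate a codebook
#'
#' @param items List of [item_def()] objects with unique ids.
#' @param version_tag Free-text version label.
#' @return Object of class `codebook`.
#' @export
codebook <- function(items, version_tag = "unversioned") {
  stopifnot(is.list(items), length(items) >= 1L)
  items <- lapply(items, function(it) {
    if (!inherits(it, "item_def"))
      it <- item_def(it$id, it$construct, it$prompt, unlist(it$option_scores))
    it
  })
  ids <- vapply(items, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate item id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(items) <- ids
  structure(list(items = items, version_tag = version_tag), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cons <- table(vapply(x$items, `[[`, character(1), "construct"))
  cat("codebook '", x$version_tag, "': ", length(x$items), " items, ",
      length(cons), " constructs\n", sep = "")
  invisible(x)
}

#' Codebook item ids
#' @param cb A `codebook`.
#' @export
item_ids <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  names(cb$items)
}

#' Read a codebook from a JSON file
#'
#' Expected schema: an object with `version_tag` and `items`, each item an
#' object with `id`, `construct`, `prompt` and `option_scores` (a label-to-
#' score map). All [item_def()] and [codebook()] invariants are enforced.
#'
#' @param path Path to a JSON codebook.
#' @return A validated `codebook`.
#' @seealso [write_codebook()]
#' @export
load_codebook <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$items)) stop("codebook file has no 'items' field")
  items <- lapply(raw$items, function(it) {
    item_def(it$id, it$construct, it$prompt %||% "", unlist(it$option_scores))
  })
  codebook(items, version_tag = raw$version_tag %||% "unversioned")
}

#' Write a codebook to JSON
#' @param cb A `codebook`.
#' @param path Output path.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  out <- list(version_tag = cb$version_tag,
              items = lapply(unname(cb$items), function(it) {
                list(id = it$id, construct = it$construct, prompt = it$prompt,
                     option_scores = as.list(it$option_scores))
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total instrument scores over an item subset
#'
#' Sums the per-item scores of each respondent over `items`. A respondent is
#' `complete` only when every subset item carries a score; totals of
#' incomplete respondents sum the items that are present and are excluded
#' from group assignment downstream (complete-case policy; no imputation).
#'
#' @param responses Data frame with `dyad_id` plus one numeric column per item
#'   id holding scores on the half-point grid in `[1, 5]`; missing = `NA`.
#' @param cb The `codebook` the responses were scored against.
#' @param items Character vector of item ids to total (e.g. a reduced
#'   instrument); must all exist in the codebook and the response table.
#' @return Data frame: `dyad_id`, `total`, `n_items`, `complete`. With a
#'   complete k-item response the total lies in `[k, 5k]`.
#' @export
score_total <- function(responses, cb, items) {
  stopifnot(is.data.frame(responses), "dyad_id" %in% names(responses))
  stopifnot(inherits(cb, "codebook"))
  unknown <- setdiff(items, item_ids(cb))
  if (length(unknown))
    stop("items not in codebook: ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(items, names(responses))
  if (length(missing_cols))
    stop("items not in response table: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(responses[, items, drop = FALSE])
  present <- !is.na(m)
  vals <- m[present]
  if (length(vals)) check_score_grid(vals, "responses")
  data.frame(dyad_id = responses$dyad_id,
             total = rowSums(m, na.rm = TRUE),
             n_items = length(items),
             complete = rowSums(present) == length(items),
             stringsAsFactors = FALSE)
}

#' Dichotomize total scores into low/high groups
#'
#' `high` iff `total >= threshold`; the threshold itself is the only boundary
#' point mapping to `high`. Incomplete totals are excluded (dropped rows) —
#' they have no defensible group.
#'
#' @param totals Output of [score_total()].
#' @param threshold Cut point in score units (default 75).
#' @return Data frame `dyad_id`, `total`, `group` (factor low/high),
#'   `threshold`, restricted to complete respondents.
#' @export
assign_group <- function(totals, threshold = 75) {
  stopifnot(is.data.frame(totals),
            all(c("dyad_id", "total", "complete") %in% names(totals)))
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  keep <- totals[totals$complete, , drop = FALSE]
  data.frame(dyad_id = keep$dyad_id, total = keep$total,
             group = factor(ifelse(keep$total >= threshold, "high", "low"),
                            levels = c("low", "high")),
             threshold = threshold, stringsAsFactors = FALSE)
}
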