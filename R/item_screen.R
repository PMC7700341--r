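#' Discretize item scores into observed-level categories
#'
#' Categories are the distinct observed score levels in ascending order;
#' levels carrying fewer than `min_count` observations are merged into the
#' nearest (by score distance, ties toward the lower) neighbouring level, for
#' stable boxplot panels. Constant items collapse to a single category.
#'
#' @param scores Numeric item scores in `[1, 5]` (`NA` dropped from counts
#'   but kept as `NA` in the output).
#' @param min_count Minimum observations per retained level (default 5).
#' @return Ordered factor of the same length as `scores`.
#' @export
discretize_item <- function(scores, min_count = 5) {
  ok <- !is.na(scores)
  if (any(scores[ok] < 1 | scores[ok] > 5)) stop("scores must lie in [1, 5]")
  levels_now <- sort(unique(scores[ok]))
  if (length(levels_now) == 0L) stop("no observed scores")
  # iteratively merge the thinnest level into its nearest neighbour
  assignment <- scores
  repeat {
    counts <- table(factor(assignment[ok], levels = levels_now))
    thin <- which(counts < min_count)
    if (length(thin) == 0L || length(levels_now) == 1L) break
    i <- thin[which.min(counts[thin])][1]
    others <- setdiff(seq_along(levels_now), i)
    j <- others[which.min(abs(levels_now[others] - levels_now[i]))]
    assignment[!is.na(assignment) & assignment == levels_now[i]] <- levels_now[j]
    levels_now <- levels_now[-i]
  }
  factor(assignment, levels = levels_now, ordered = TRUE)
}

#' Screen one item against anthropometric markers
#'
#' Rank-based stand-in for the visual boxplot judgement used in item
#' reduction: for each marker the Spearman correlation between the item score
#' and the marker is computed, and the item is kept when at least one marker
#' shows the healthful inverse trend — `rho <= -rho_min` together with a
#' one-sided (negative) normal-approximation p-value at or below
#' `alpha_screen`, so that a pure-noise item survives at roughly the
#' `alpha_screen` rate. Setting `alpha_screen = 1` reduces the rule to the
#' raw magnitude threshold alone. Decisions are invariant to strictly
#' increasing transforms of the markers.
#'
#' @param item_scores Numeric scores for one item.
#' @param markers Data frame of marker columns (e.g. `bmi_percentile`,
#'   `bmi_z`, `whtr`), rows aligned with `item_scores`.
#' @param rho_min Minimum magnitude of the negative Spearman correlation
#'   (default 0.05).
#' @param alpha_screen One-sided significance bound for the trend
#'   (default 0.05).
#' @param min_pairs Minimum complete pairs required per marker (default 20).
#' @param min_count Passed to [discretize_item()]; an item collapsing to a
#'   single category is dropped.
#' @return List: `kept` (logical), `reason`, `stats` (per-marker data frame
#'   with `rho`, `n`, `p_one_sided`, `passes`).
#' @export
screen_item <- function(item_scores, markers, rho_min = 0.05,
                        alpha_screen = 0.05, min_pairs = 20, min_count = 5) {
  stopifnot(is.data.frame(markers), nrow(markers) == length(item_scores))
  cats <- discretize_item(item_scores, min_count = min_count)
  if (nlevels(cats) < 2L)
    return(list(kept = FALSE, reason = "single category after discretization",
                stats = NULL))
  st <- do.call(rbind, lapply(names(markers), function(mk) {
    y <- markers[[mk]]
    ok <- !is.na(item_scores) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs)
      return(data.frame(marker = mk, rho = NA_real_, n = n,
                        p_one_sided = NA_real_, passes = FALSE))
    rho <- stats::cor(item_scores[ok], y[ok], method = "spearman")
    # normal approximation, robust to the heavy ties of a 5-level item
    p <- stats::pnorm(rho * sqrt(n - 1))
    data.frame(marker = mk, rho = rho, n = n, p_one_sided = p,
               passes = !is.na(rho) & rho <= -rho_min & p <= alpha_screen)
  }))
  if (all(!is.na(st$rho) == FALSE))
    return(list(kept = FALSE, reason = "insufficient paired observations", stats = st))
  list(kept = any(st$passes), reason = if (any(st$passes)) "inverse trend" else "no inverse trend",
       stats = st)
}

#' Screen every item of an instrument pool
#'
#' @param responses Scored response table (`dyad_id` + one column per item).
#' @param cb Codebook covering the pool (supplies construct labels).
#' @param markers_by_dyad Data frame with `dyad_id` and marker columns
#'   (typically `bmi_percentile`, `bmi_z`, `whtr` from [derive_anthro()]).
#' @param items Item ids to screen (default: all codebook items).
#' @inheritParams screen_item
#' @return Data frame, one row per item: `item`, `construct`, `kept`,
#'   `reason`, `best_rho` (most negative marker correlation) and per-marker
#'   `rho_<marker>` columns.
#' @export
screen_items <- function(responses, cb, markers_by_dyad, items = item_ids(cb),
                         rho_min = 0.05, alpha_screen = 0.05,
                         min_pairs = 20, min_count = 5) {
  stopifnot("dyad_id" %in% names(markers_by_dyad))
  mk_cols <- setdiff(names(markers_by_dyad), "dyad_id")
  idx <- match(responses$dyad_id, markers_by_dyad$dyad_id)
  markers <- markers_by_dyad[idx, mk_cols, drop = FALSE]
  rows <- lapply(items, function(it) {
    res <- screen_item(responses[[it]], markers, rho_min = rho_min,
                       alpha_screen = alpha_screen, min_pairs = min_pairs,
                       min_count = min_count)
    rhos <- if (is.null(res$stats)) stats::setNames(rep(NA_real_, length(mk_cols)), mk_cols)
            else stats::setNames(res$stats$rho, res$stats$marker)
    out <- data.frame(item = it, construct = cb$items[[it]]$construct,
                      kept = res$kept, reason = res$reason,
                      best_rho = if (all(is.na(rhos))) NA_real_ else min(rhos, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    for (mk in mk_cols) out[[paste0("rho_", mk)]] <- unname(rhos[mk])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduce a screened pool to a parsimonious instrument
#'
#' Keeps every item passing the screen. If more pass than `size_range[2]`,
#' the weakest items (largest `best_rho`, i.e. least negative) are pruned —
#' honouring optional per-construct caps first — until the pool fits;
#' within-construct ordering is by strongest negative correlation, ties
#' broken lexicographically by item id. If fewer pass than `size_range[1]`,
#' all passing items are returned with `under_minimum = TRUE`.
#'
#' @param screen_results Output of [screen_items()].
#' @param size_range Target instrument size, `c(min, max)` (default 16-20).
#' @param construct_caps Optional named integer vector capping items per
#'   construct.
#' @return List: `items` (selected ids), `by_construct` (table of counts),
#'   `under_minimum` (logical), `screen` (annotated input with a `selected`
#'   column).
#' @export
reduce_pool <- function(screen_results, size_range = c(16, 20),
                        construct_caps = NULL) {
  stopifnot(all(c("item", "construct", "kept", "best_rho") %in% names(screen_results)))
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  pool <- screen_results[screen_results$kept, , drop = FALSE]
  # deterministic strength order: strongest (most negative) first, id tie-break
  pool <- pool[order(pool$best_rho, pool$item), , drop = FALSE]
  if (!is.null(construct_caps)) {
    keep <- unlist(lapply(split(seq_len(nrow(pool)), pool$construct), function(ix) {
      cons <- pool$construct[ix[1]]
      cap <- if (cons %in% names(construct_caps)) construct_caps[[cons]] else NA
      if (is.na(cap)) ix else ix[seq_len(min(length(ix), cap))]
    }))
    pool <- pool[sort(keep), , drop = FALSE]
  }
  if (nrow(pool) > size_range[2])
    pool <- pool[seq_len(size_range[2]), , drop = FALSE]
  sel <- pool$item
  screen_results$selected <- screen_results$item %in% sel
  list(items = sort(sel),
       by_construct = table(pool$construct),
       under_minimum = length(sel) < size_range[1],
       screen = screen_results)
}

#' Boxplots of a marker across item-score categories
#'
#' Visual companion to [screen_item()] (rendering only; decisions are always
#' the rank-based rule). Whiskers extend to 1.5 IQR, the convention of
#' [flag_outliers()].
#'
#' @inheritParams screen_item
#' @param marker Numeric marker vector aligned with `item_scores`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_item_boxplot <- function(item_scores, marker, min_count = 5, ...) {
  cats <- discretize_item(item_scores, min_count = min_count)
  graphics::boxplot(marker ~ cats, range = 1.5, ...)
}
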