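# Leakage-aware partitioning: mapping points identifying the same VT critical
# site share a group_id and are never split across train/test or CV folds.

#' Grouped train/test split
#'
#' Positives are split at the granularity of their VT-site group (a group is
#' entirely in train or entirely in test); negatives are split at row level.
#'
#' @param table feature tibble with `label` and `group_id`.
#' @param frac training fraction (default 0.8).
#' @param seed RNG seed.
#' @return A `vts_split`: list with integer row indices `train` and `test`.
#' @export
grouped_split <- function(table, frac = 0.8, seed = 1L) {
  pos_groups <- unique(table$group_id[table$label == 1L])
  if (length(pos_groups) < 2L) abort("need at least 2 positive groups to split")
  withr::with_seed(seed, {
    n_tr_g <- round(frac * length(pos_groups))
    n_tr_g <- min(max(n_tr_g, 1L), length(pos_groups) - 1L)
    tr_groups <- sample(pos_groups, n_tr_g)
    pos_rows <- which(table$label == 1L)
    neg_rows <- which(table$label == 0L)
    tr_pos <- pos_rows[table$group_id[pos_rows] %in% tr_groups]
    tr_neg <- sample(neg_rows, round(frac * length(neg_rows)))
    train <- sort(c(tr_pos, tr_neg))
  })
  structure(list(train = train, test = setdiff(seq_len(nrow(table)), train),
                 frac = frac, seed = seed),
            class = "vts_split")
}

#' Repeated grouped cross-validation folds
#'
#' k-fold assignments repeated `repeats` times over the training rows.
#' Positive rows are allocated fold-wise by VT-site group (no group spans
#' folds); negative rows are randomized afresh in every repeat.
#'
#' @param table feature tibble with `label` and `group_id`.
#' @param rows training row indices (e.g. `split$train`).
#' @param k folds (default 10).
#' @param repeats repeats (default 10).
#' @param seed RNG seed.
#' @return A `vts_folds`: list of integer fold vectors (one per repeat,
#'   aligned with `rows`), with `rows` attached.
#' @export
make_folds <- function(table, rows, k = 10L, repeats = 10L, seed = 1L) {
  lab <- table$label[rows]
  grp <- table$group_id[rows]
  pos_groups <- unique(grp[lab == 1L])
  if (length(pos_groups) < k) {
    abort(sprintf("need >= %d positive groups for %d folds (have %d)",
                  k, k, length(pos_groups)))
  }
  withr::with_seed(seed, {
    plans <- lapply(seq_len(repeats), function(r) {
      fold <- integer(length(rows))
      g_fold <- setNames(
        rep_len(seq_len(k), length(pos_groups))[sample.int(length(pos_groups))],
        sample(pos_groups))
      is_pos <- lab == 1L
      fold[is_pos] <- g_fold[grp[is_pos]]
      n_neg <- sum(!is_pos)
      fold[!is_pos] <- rep_len(seq_len(k), n_neg)[sample.int(n_neg)]
      fold
    })
  })
  structure(plans, rows = rows, k = k, class = "vts_folds")
}

#' Stratified class undersampling
#'
#' Keeps every positive row and samples negatives without replacement down to
#' the requested positive:negative ratio, stratified by map (each map
#' contributes negatives proportionally to its share, exact total by largest
#' remainder). If there are not enough negatives, all are kept with a
#' warning.
#'
#' @param table feature tibble with `label` and `map_id`.
#' @param rows candidate row indices.
#' @param ratio `"none"`, `"1:1"` or `"1:5"` (positive:negative).
#' @param seed RNG seed.
#' @return Integer vector of retained row indices (sorted).
#' @export
undersample <- function(table, rows, ratio = c("none", "1:1", "1:5"), seed = 1L) {
  ratio <- match.arg(ratio)
  if (ratio == "none") return(rows)
  r <- as.integer(sub("^1:", "", ratio))
  pos <- rows[table$label[rows] == 1L]
  neg <- rows[table$label[rows] == 0L]
  target <- r * length(pos)
  if (length(neg) <= target) {
    if (length(neg) < target) warn("not enough negatives for the requested ratio; keeping all")
    return(sort(c(pos, neg)))
  }
  withr::with_seed(seed, {
    maps <- table$map_id[neg]
    tab <- table(maps)
    quota_real <- as.numeric(tab) / length(neg) * target
    quota <- floor(quota_real)
    rem <- target - sum(quota)
    if (rem > 0L) {
      extra <- order(quota_real - quota, decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    sel <- unlist(lapply(seq_along(tab), function(i) {
      cand <- neg[maps == names(tab)[i]]
      sample(cand, min(quota[i], length(cand)))
    }))
    # top up if any stratum was short
    if (length(sel) < target) {
      pool <- setdiff(neg, sel)
      sel <- c(sel, sample(pool, target - length(sel)))
    }
  })
  sort(c(pos, sel))
}
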