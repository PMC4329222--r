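# Attribute, sub-band and feature-pair selection.
#
# Correlation-based feature selection (CFS) scores a subset by how strongly
# its features correlate with the class and how weakly they correlate with
# each other. Pearson correlation against the binary 0/1 class label is the
# point-biserial correlation. Subset search is best-first (with a stall
# limit) or greedy forward; the consensus of the two searches, topped up by
# pooled-variance |t| rank, reduces the 19 texture features to a target
# count (11 by default). An exhaustive cross-validated search over feature
# pairs then picks the SVM input.

#' Labelled feature matrix
#'
#' @param x Numeric matrix, samples in rows, named feature columns; no
#'   missing values.
#' @param labels Binary 0/1 class labels (1 = nodule), one per row.
#' @return Object of class `feature_matrix` with fields `x`, `labels`.
#' @export
feature_matrix <- function(x, labels) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stopf("`x` needs unique column names")
  }
  if (anyNA(x) || !all(is.finite(x))) stopf("`x` must be finite, no NAs")
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stopf("one label per row required")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

# Absolute Pearson correlation tables; zero-variance features get 0.
.fm_correlations <- function(fm) {
  x <- fm$x
  y <- as.double(fm$labels)
  rcf <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
  rcf[!is.finite(rcf)] <- 0
  names(rcf) <- colnames(x)
  rff <- suppressWarnings(abs(stats::cor(x)))
  rff[!is.finite(rff)] <- 0
  diag(rff) <- 1
  list(rcf = rcf, rff = rff)
}

#' CFS merit of a feature subset
#'
#' `merit = k * mean|r_cf| / sqrt(k + k (k - 1) * mean|r_ff|)` where
#' `r_cf` are the feature-class correlations (point-biserial for the binary
#' class) and `r_ff` the pairwise feature-feature correlations of the
#' subset. Reduces to `|r_cf|` for a singleton.
#'
#' @param fm A [feature_matrix].
#' @param subset Non-empty character vector of feature names.
#' @param cors Optional precomputed correlation tables (internal reuse).
#' @return Scalar merit.
#' @export
cfs_merit <- function(fm, subset, cors = .fm_correlations(fm)) {
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stopf("`subset` must be non-empty")
  if (!all(subset %in% names(cors$rcf))) stopf("unknown feature in subset")
  k <- length(subset)
  rcf_bar <- mean(cors$rcf[subset])
  if (k == 1L) return(rcf_bar)
  R <- cors$rff[subset, subset]
  rff_bar <- mean(R[upper.tri(R)])
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

.subset_key <- function(s) paste(sort(s), collapse = "|")

#' Best-first CFS subset search
#'
#' Starts from the empty set and expands the best unexpanded subset by
#' single-feature additions and removals, keeping the highest-merit subset
#' seen; terminates after `stall_limit` consecutive non-improving
#' expansions. Fully deterministic: candidate features are tried in
#' lexicographic order and ties break lexicographically on the subset key.
#'
#' @param fm A [feature_matrix].
#' @param stall_limit Non-improving expansions tolerated (default 5).
#' @return List with `selected` (feature names), `merit`, `scores`
#'   (per-selected-feature class correlation) and `trace` (data frame of
#'   evaluated subsets and merits).
#' @export
best_first_select <- function(fm, stall_limit = 5L) {
  cors <- .fm_correlations(fm)
  feats <- sort(colnames(fm$x))
  evaluated <- new.env(parent = emptyenv())
  trace_keys <- character(0); trace_merits <- numeric(0)
  merit_of <- function(s) {
    key <- paste0("k:", .subset_key(s))
    if (!is.null(evaluated[[key]])) return(evaluated[[key]])
    m <- if (length(s) == 0L) 0 else cfs_merit(fm, s, cors)
    evaluated[[key]] <- m
    trace_keys <<- c(trace_keys, .subset_key(s))
    trace_merits <<- c(trace_merits, m)
    m
  }
  open_keys <- .subset_key(character(0))
  open_sets <- list(character(0))
  open_merits <- merit_of(character(0))
  expanded <- new.env(parent = emptyenv())
  best_set <- character(0); best_merit <- 0
  stall <- 0L
  while (length(open_sets) > 0L && stall <= stall_limit) {
    ord <- order(-open_merits, open_keys)
    pick <- ord[1]
    s <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_merits <- open_merits[-pick]
    open_keys <- open_keys[-pick]
    skey <- paste0("k:", .subset_key(s))
    if (!is.null(expanded[[skey]])) next
    expanded[[skey]] <- TRUE
    improved <- FALSE
    children <- c(lapply(setdiff(feats, s), function(f) sort(c(s, f))),
                  if (length(s) > 1L) lapply(s, function(f) setdiff(s, f)))
    for (child in children) {
      ckey <- .subset_key(child)
      if (!is.null(expanded[[paste0("k:", ckey)]]) || ckey %in% open_keys) next
      m <- merit_of(child)
      open_sets <- c(open_sets, list(child))
      open_merits <- c(open_merits, m)
      open_keys <- c(open_keys, ckey)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  if (length(best_set) == 0L) {
    best_set <- feats[which.max(cors$rcf[feats])]
    best_merit <- cors$rcf[best_set]
  }
  list(selected = sort(best_set), merit = unname(best_merit),
       scores = cors$rcf[sort(best_set)],
       trace = data.frame(subset = trace_keys, merit = trace_merits,
                          stringsAsFactors = FALSE))
}

#' Greedy forward CFS subset search
#'
#' Strictly additive: at every step the single feature whose addition most
#' improves the CFS merit is added (lexicographic tie-break); stops when no
#' addition improves. When no single feature has positive merit the best
#' singleton is returned.
#'
#' @inheritParams best_first_select
#' @return Same shape as [best_first_select()].
#' @export
greedy_forward_select <- function(fm) {
  cors <- .fm_correlations(fm)
  feats <- sort(colnames(fm$x))
  sel <- character(0)
  merit <- 0
  trace_keys <- character(0); trace_merits <- numeric(0)
  repeat {
    cand <- setdiff(feats, sel)
    if (length(cand) == 0L) break
    merits <- vapply(cand, function(f) cfs_merit(fm, c(sel, f), cors),
                     numeric(1))
    trace_keys <- c(trace_keys,
                    vapply(cand, function(f) .subset_key(c(sel, f)),
                           character(1)))
    trace_merits <- c(trace_merits, merits)
    bi <- which(merits == max(merits))[1]  # cand is sorted: lexicographic tie
    if (merits[bi] <= merit + 1e-12) break
    sel <- sort(c(sel, cand[bi]))
    merit <- merits[bi]
  }
  if (length(sel) == 0L) {
    sel <- feats[which.max(cors$rcf[feats])]
    merit <- unname(cors$rcf[sel])
  }
  list(selected = sel, merit = unname(merit), scores = cors$rcf[sel],
       trace = data.frame(subset = trace_keys, merit = trace_merits,
                          stringsAsFactors = FALSE))
}

#' Rank features by pooled-variance two-sample |t|
#'
#' For each feature, `t = (mean_1 - mean_0) / (s_p sqrt(1/n_1 + 1/n_0))`
#' with the pooled standard deviation `s_p`; features are ordered by
#' descending `|t|` (lexicographic tie-break). A zero pooled variance gives
#' score 0 when the class means are equal and `Inf` (ranked first) when
#' they differ.
#'
#' @param fm A [feature_matrix] with at least 2 samples per class.
#' @return Data frame with columns `feature`, `t_abs`, ordered best first.
#' @export
tstat_rank <- function(fm) {
  y <- fm$labels
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stopf("need >= 2 samples per class for t ranking")
  }
  x1 <- fm$x[y == 1L, , drop = FALSE]
  x0 <- fm$x[y == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2, stats::var); v0 <- apply(x0, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  t_abs <- ifelse(sp2 > 0,
                  abs(m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0)),
                  ifelse(abs(m1 - m0) > 0, Inf, 0))
  out <- data.frame(feature = colnames(fm$x), t_abs = unname(t_abs),
                    stringsAsFactors = FALSE)
  out[order(-out$t_abs, out$feature), , drop = FALSE]
}

#' Consensus attribute selection to a target count
#'
#' Runs best-first and greedy-forward CFS searches, keeps the features
#' chosen by both, and tops up (or trims) to `n_target` by |t| rank. This
#' is the mechanism that reduces the 19 texture features to 11.
#'
#' @param fm A [feature_matrix].
#' @param n_target Target attribute count (default 11).
#' @return List with `selected`, `t_rank` (full [tstat_rank()] table),
#'   `best_first`, `greedy` (the two search results).
#' @export
select_attributes <- function(fm, n_target = 11L) {
  n_target <- min(as.integer(n_target), ncol(fm$x))
  bf <- best_first_select(fm)
  gr <- greedy_forward_select(fm)
  tr <- tstat_rank(fm)
  core <- intersect(bf$selected, gr$selected)
  sel <- tr$feature[tr$feature %in% core]
  if (length(sel) > n_target) {
    sel <- sel[seq_len(n_target)]
  } else if (length(sel) < n_target) {
    extra <- tr$feature[!(tr$feature %in% sel)]
    sel <- c(sel, extra[seq_len(n_target - length(sel))])
  }
  list(selected = sel, t_rank = tr, best_first = bf, greedy = gr)
}

# Deterministic stratified fold assignment (1..folds per sample).
.stratified_folds <- function(labels, folds, seed) {
  folds <- min(folds, max(2L, min(table(labels))))
  assign <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

#' Exhaustive feature-pair search
#'
#' Evaluates every unordered pair of candidate features by stratified
#' k-fold cross-validated accuracy of an RBF-SVM (fixed `cost`/`sigma`,
#' per-fold z-standardization) and returns the best pair. Ties break by
#' higher summed |t| rank, then lexicographically.
#'
#' @param fm A [feature_matrix].
#' @param candidates Candidate feature names (>= 2); default all columns.
#' @param folds CV folds (default 5; reduced if a class is smaller).
#' @param seed Fold-assignment seed.
#' @param cost,sigma SVM hyperparameters used during pair scoring.
#' @return List with `pair` (length-2 character), `accuracy` (CV accuracy
#'   of the winner) and `trace` (data frame of all
#'   `choose(length(candidates), 2)` evaluations).
#' @export
select_pair <- function(fm, candidates = colnames(fm$x), folds = 5L,
                        seed = 1L, cost = 100, sigma = 4) {
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) < 2L) stopf("need >= 2 candidate features")
  pairs <- utils::combn(candidates, 2L)
  fold_id <- .stratified_folds(fm$labels, folds, seed)
  y <- fm$labels
  # standardization is per-feature, so it can be hoisted out of the pair
  # loop: standardize the full candidate matrix once per fold
  fold_split <- lapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    X <- fm$x[, candidates, drop = FALSE]
    std <- .standardize_fit(X[tr, , drop = FALSE])
    list(ztr = std$z, zte = .standardize_apply(std, X[!tr, , drop = FALSE]),
         ytr = y[tr], yte = y[!tr])
  })
  acc <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    correct <- 0L
    for (fs in fold_split) {
      fit <- .svm_fit(fs$ztr[, pairs[, p], drop = FALSE], fs$ytr,
                      cost = cost, sigma = sigma)
      pred <- .svm_score(fit, fs$zte[, pairs[, p], drop = FALSE]) > 0
      correct <- correct + sum(pred == fs$yte)
    }
    acc[p] <- correct / length(y)
  }
  tr_rank <- tstat_rank(fm)
  rank_of <- stats::setNames(seq_len(nrow(tr_rank)), tr_rank$feature)
  rank_sum <- rank_of[pairs[1, ]] + rank_of[pairs[2, ]]
  key <- paste(pairs[1, ], pairs[2, ])
  ord <- order(-acc, rank_sum, key)
  best <- ord[1]
  list(pair = pairs[, best], accuracy = acc[best],
       trace = data.frame(feature_1 = pairs[1, ], feature_2 = pairs[2, ],
                          cv_accuracy = acc, stringsAsFactors = FALSE))
}
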