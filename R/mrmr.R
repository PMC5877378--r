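#' Discretize features for mutual-information estimation
#'
#' Default scheme: three levels per feature split at mean - sd and
#' mean + sd (values <= mu - sigma -> 0, >= mu + sigma -> 2, else 1),
#' following the original MRMR discretization practice. Alternatively,
#' equal-frequency quantile binning with any number of levels. Constant
#' features collapse to a single level and are flagged.
#'
#' @param X numeric matrix (epochs x features) or a `feature_matrix`.
#' @param n_levels number of levels (>= 2); the `"musd"` method requires 3.
#' @param method `"musd"` (mean +/- sd) or `"quantile"` (equal frequency).
#' @return a `discretized_features` list: `codes` (integer matrix, values in
#'   `0:(n_levels-1)`), `edges` per feature, `n_levels`, and `flagged`
#'   (logical, constant features).
#' @export
discretize_features <- function(X, n_levels = 3,
                                method = c("musd", "quantile")) {
  method <- match.arg(method)
  if (inherits(X, "feature_matrix")) X <- X$X
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (method == "musd" && n_levels != 3) {
    stop("the mean +/- sd scheme defines exactly 3 levels")
  }
  nf <- ncol(X)
  codes <- matrix(0L, nrow(X), nf, dimnames = dimnames(X))
  edges <- vector("list", nf)
  flagged <- setNames(logical(nf), colnames(X))
  for (j in seq_len(nf)) {
    x <- X[, j]
    if (method == "musd") {
      mu <- mean(x); s <- stats::sd(x)
      if (!is.finite(s) || s == 0) { flagged[j] <- TRUE; edges[[j]] <- c(mu, mu); next }
      edges[[j]] <- c(mu - s, mu + s)
      codes[, j] <- as.integer(x > mu - s) + as.integer(x >= mu + s)
    } else {
      qs <- stats::quantile(x, probs = seq_len(n_levels - 1) / n_levels,
                            names = FALSE)
      if (length(unique(x)) == 1) { flagged[j] <- TRUE; edges[[j]] <- qs; next }
      edges[[j]] <- qs
      codes[, j] <- findInterval(x, qs, left.open = TRUE)
    }
  }
  structure(list(codes = codes, edges = edges, n_levels = n_levels,
                 flagged = flagged),
            class = "discretized_features")
}

#' Plug-in mutual information of two discrete series
#'
#' Estimated in nats from the joint contingency table:
#' `I(x;y) = sum p(x,y) log(p(x,y) / (p(x) p(y)))`. Always >= 0 and
#' symmetric; 0 when either series is constant, and `I(x;x) = H(x)`.
#'
#' @param x,y equal-length vectors coercible to factors.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) == 0) stop("empty input")
  ix <- as.integer(factor(x)); iy <- as.integer(factor(y))
  nx <- max(ix); ny <- max(iy)
  joint <- tabulate(ix + nx * (iy - 1L), nbins = nx * ny) / length(x)
  px <- tabulate(ix, nx) / length(x)
  py <- tabulate(iy, ny) / length(y)
  pp <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

mi_columns <- function(codes, y) {
  vapply(seq_len(ncol(codes)),
         function(j) mutual_information(codes[, j], y), numeric(1))
}

#' MRMR greedy forward feature ranking
#'
#' Ranks features by minimal-redundancy-maximal-relevance: the first
#' feature maximizes relevance `I(x; y)`; each subsequent feature maximizes
#' `I(x_j; y) - (1/k) * sum_{i in S} I(x_j; x_i)` over the features not yet
#' selected, where `S` is the current selection of size `k`. Ties are broken
#' by the lower feature index.
#'
#' @param disc a [discretize_features()] result (or integer code matrix).
#' @param labels class labels, one per row of the code matrix.
#' @param k number of features to rank (default: all).
#' @param redundancy_weight weight on the redundancy term (1 = standard
#'   MRMR; 0 reduces the ranking to pure relevance ordering).
#' @return a `feature_ranking`: `order` (feature indices, best first),
#'   `names`, `score` (the criterion value when selected), and `relevance`
#'   (`I(x; y)` for every feature).
#' @export
mrmr_rank <- function(disc, labels, k = NULL, redundancy_weight = 1) {
  codes <- if (inherits(disc, "discretized_features")) disc$codes else disc
  nf <- ncol(codes)
  if (is.null(k)) k <- nf
  if (k <= 0) stop("k must be positive")
  if (k > nf) stop("k (", k, ") exceeds the number of features (", nf, ")")
  if (nrow(codes) != length(labels)) stop("labels length mismatch")
  relevance <- mi_columns(codes, labels)
  order <- integer(k)
  score <- numeric(k)
  redsum <- numeric(nf)
  remaining <- rep(TRUE, nf)
  for (step in seq_len(k)) {
    crit <- if (step == 1) relevance else
      relevance - redundancy_weight * redsum / (step - 1)
    crit[!remaining] <- -Inf
    best <- which.max(crit)           # which.max takes the lowest index on ties
    order[step] <- best
    score[step] <- crit[best]
    remaining[best] <- FALSE
    if (step < k && redundancy_weight != 0) {
      sel <- codes[, best]
      upd <- which(remaining)
      redsum[upd] <- redsum[upd] +
        vapply(upd, function(j) mutual_information(codes[, j], sel),
               numeric(1))
    }
  }
  structure(list(order = order, names = colnames(codes)[order],
                 score = score, relevance = relevance),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d ranked features; top 5: %s\n",
              length(x$order),
              paste(utils::head(x$names, 5), collapse = ", ")))
  invisible(x)
}

#' Aggregate per-subject rankings into a cohort top-feature list
#'
#' Counts, for every feature, how many subjects place it inside their own
#' top-`top_n`, and returns the `top_n` features by appearance count (ties
#' broken by mean rank across the subjects that selected the feature, then
#' by feature index), mapped to electrode and feature family.
#'
#' @param rankings list of per-subject `feature_ranking` objects over the
#'   same feature set.
#' @param top_n size of the per-subject and aggregated lists (default 20).
#' @return data.frame with `feature`, `electrode`, `family`, `n_subjects`,
#'   `mean_rank`, ordered best first.
#' @export
aggregate_top_electrodes <- function(rankings, top_n = 20) {
  if (length(rankings) == 0) stop("no rankings supplied")
  nm <- rankings[[1]]$names
  all_names <- character(0)
  for (r in rankings) {
    if (length(r$order) < top_n) {
      stop("ranking has fewer than top_n = ", top_n, " entries")
    }
  }
  feats <- sort(unique(unlist(lapply(rankings,
                                     function(r) r$names[seq_len(top_n)]))))
  count <- setNames(integer(length(feats)), feats)
  ranksum <- setNames(numeric(length(feats)), feats)
  for (r in rankings) {
    top <- r$names[seq_len(top_n)]
    count[top] <- count[top] + 1L
    ranksum[top] <- ranksum[top] + seq_len(top_n)
  }
  mean_rank <- ranksum / count
  ord <- order(-count, mean_rank, match(feats, nm))
  sel <- feats[ord][seq_len(min(top_n, length(feats)))]
  info <- feature_info(sel)
  data.frame(info, n_subjects = as.integer(count[sel]),
             mean_rank = as.numeric(mean_rank[sel]),
             row.names = NULL, stringsAsFactors = FALSE)
}
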