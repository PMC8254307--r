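# Random-forest model of duplicated-region length on features of the
# untrimmed SD network, with permutation-based importance p-values.

#' Extract per-region features from the untrimmed network
#'
#' One row per node: node degree (distinct neighbours), connected-component
#' size, fraction of intrachromosomal edges, self-loop count, double-edge
#' count (sum over neighbours of multiplicity - 1; both loop counts exist
#' only in the untrimmed network), optional mean copy number, and the
#' response `length` (bp).
#'
#' @param net `sd_network` (keeps its untrimmed multiplicities).
#' @param copy_number optional numeric vector of per-region mean copy
#'   numbers (same order as `net$nodes`); when NULL the feature is
#'   omitted with a warning.
#' @return data.frame of features plus `length`.
#' @export
extract_region_features <- function(net, copy_number = NULL) {
  stopifnot(inherits(net, "sd_network"))
  nd <- net$nodes
  n <- nrow(nd)
  comp <- igraph::components(net$graph)
  double_edges <- numeric(n)
  intra_edges <- numeric(n)
  if (nrow(net$edges)) {
    extra <- net$edges$multiplicity - 1L
    same_chrom <- as.integer(nd$chrom[net$edges$a] == nd$chrom[net$edges$b])
    # each edge contributes to both endpoints
    for (side in c("a", "b")) {
      idx <- factor(net$edges[[side]], levels = seq_len(n))
      double_edges <- double_edges +
        as.numeric(tapply(extra, idx, sum, default = 0))
      intra_edges <- intra_edges +
        as.numeric(tapply(same_chrom, idx, sum, default = 0))
    }
  }
  self_loops <- numeric(n)
  if (length(net$self_loops))
    self_loops[as.integer(names(net$self_loops))] <- net$self_loops
  df <- data.frame(
    degree = nd$degree,
    component_size = comp$csize[comp$membership],
    intra_fraction = ifelse(nd$degree > 0, intra_edges / nd$degree, 0),
    self_loops = self_loops,
    double_edges = double_edges,
    length = nd$length)
  if (is.null(copy_number)) {
    warning("no copy-number track supplied; feature omitted")
  } else {
    stopifnot(length(copy_number) == n)
    df$copy_number <- copy_number
  }
  df[, c(setdiff(names(df), "length"), "length")]
}

#' Cross-validated random-forest fit of region length
#'
#' Random-forest regression (500 trees) of `length` on all other columns;
#' reports the out-of-fold R-squared averaged over `n_folds`
#' cross-validation folds.
#'
#' @param features data.frame from [extract_region_features()].
#' @param n_folds number of CV folds.
#' @param n_trees forest size.
#' @param seed RNG seed.
#' @return list `r_squared` (mean out-of-fold), `per_fold`, `model`
#'   (forest refit on all rows).
#' @export
fit_length_model <- function(features, n_folds = 10, n_trees = 500,
                             seed = NULL) {
  stopifnot(nrow(features) >= n_folds)
  if (stats::var(features$length) == 0) stop("constant response")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), nrow(features)))
  r2 <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    train <- features[folds != k, , drop = FALSE]
    test <- features[folds == k, , drop = FALSE]
    fit <- ranger::ranger(length ~ ., data = train, num.trees = n_trees,
                          seed = sample.int(1e6, 1))
    pred <- stats::predict(fit, data = test)$predictions
    r2[k] <- 1 - sum((test$length - pred)^2) /
      sum((test$length - mean(train$length))^2)
  }
  full <- ranger::ranger(length ~ ., data = features, num.trees = n_trees,
                         importance = "permutation",
                         seed = sample.int(1e6, 1))
  list(r_squared = mean(r2), per_fold = r2, model = full)
}

#' Permutation p-values for feature importances
#'
#' Reference importances come from a forest fit on the intact data
#' (out-of-bag permutation importance). The response is then shuffled
#' `n_perm` times, the forest refit each time, and the p-value of feature
#' i is the fraction of shuffled fits whose importance exceeds the
#' reference: `p = sum(imp_perm > imp_ref) / n_perm`.
#'
#' @param features data.frame from [extract_region_features()].
#' @param n_perm number of response shuffles (paper scale: 1000).
#' @param n_trees forest size per fit.
#' @param seed RNG seed.
#' @param alpha significance level annotated in the output.
#' @return data.frame `feature`, `importance`, `p_value`, `significant`.
#' @export
permutation_importance_pvalues <- function(features, n_perm = 1000,
                                           n_trees = 500, seed = NULL,
                                           alpha = 0.01) {
  if (n_perm < 100)
    warning("fewer than 100 permutations limits p-value resolution")
  if (!is.null(seed)) set.seed(seed)
  ref <- ranger::ranger(length ~ ., data = features, num.trees = n_trees,
                        importance = "permutation",
                        seed = sample.int(1e6, 1))$variable.importance
  exceed <- setNames(numeric(length(ref)), names(ref))
  shuffled <- features
  for (j in seq_len(n_perm)) {
    shuffled$length <- sample(features$length)
    imp <- ranger::ranger(length ~ ., data = shuffled,
                          num.trees = n_trees,
                          importance = "permutation",
                          seed = sample.int(1e6, 1))$variable.importance
    exceed <- exceed + as.numeric(imp[names(ref)] > ref)
  }
  p <- exceed / n_perm
  # a feature the reference forest never used (importance <= 0, e.g. a
  # constant column) trivially beats its permutations; never call it
  # significant
  data.frame(feature = names(ref), importance = as.numeric(ref),
             p_value = as.numeric(p),
             significant = as.numeric(p) < alpha & as.numeric(ref) > 0,
             row.names = NULL)
}
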