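#' Ward clustering of MDS scores with a variance-explained profile
#'
#' Agglomerative clustering on the Euclidean distances of the score
#' matrix under Ward's minimum-variance criterion (the squared-distance
#' "Ward.D2" formulation). Cluster ids are relabeled by descending
#' cluster size so labels are stable across runs. The `r2_profile`
#' reports, for each candidate number of clusters up to `k_max`, the
#' fraction of total score variance captured between clusters.
#'
#' @param scores n x d numeric matrix (finite)
#' @param k number of clusters to cut
#' @param k_max profile length (default `max(k, 10)`, capped at `n`)
#' @return object of class `cluster_result`: `labels` (size-ordered),
#'   `k`, `r2` (at `k`), `r2_profile` (k = 1..k_max), `hclust` (the
#'   linkage record)
#' @export
ward_cluster <- function(scores, k, k_max = max(k, 10L)) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  n <- nrow(scores)
  if (k < 1L || k > n) stop("k must be between 1 and n = ", n)
  k_max <- min(as.integer(k_max), n)
  h <- stats::hclust(stats::dist(scores), method = "ward.D2")
  labels <- relabel_by_size(stats::cutree(h, k))
  names(labels) <- rownames(scores)
  prof <- vapply(seq_len(k_max), function(kk)
    cluster_r2(scores, stats::cutree(h, kk)), numeric(1))
  structure(list(labels = labels, k = as.integer(k),
                 r2 = cluster_r2(scores, labels),
                 r2_profile = prof, hclust = h),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Ward clustering: k =", x$k, "clusters, R^2 =",
      sprintf("%.3f", x$r2), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

# between-cluster sum of squares / total sum of squares of the scores
cluster_r2 <- function(scores, labels) {
  scores <- as.matrix(scores)
  ctr <- colMeans(scores)
  tss <- sum(sweep(scores, 2, ctr)^2)
  if (tss == 0) return(0)
  bss <- sum(vapply(split(seq_len(nrow(scores)), labels), function(idx) {
    m <- colMeans(scores[idx, , drop = FALSE])
    length(idx) * sum((m - ctr)^2)
  }, numeric(1)))
  bss / tss
}

# relabel cluster ids 1..k by descending size (ties by original id)
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  unname(map[as.character(labels)])
}

#' Choose the number of clusters where variance explained levels off
#'
#' Elbow rule on the variance-explained profile: scanning k = 3, 4, ...,
#' the selected k is the first after which the marginal gain collapses --
#' the gain of moving to k + 1 clusters is at most `frac` (default 0.25)
#' of the gain of moving to k. A profile with no such drop (e.g. a linear
#' profile) returns 1 with a warning.
#'
#' @param r2_profile numeric vector, `r2_profile[k]` = R-squared at k
#'   clusters (so `r2_profile[1]` is 0)
#' @param frac drop threshold as a fraction of the previous gain
#' @return the selected number of clusters
#' @export
select_k <- function(r2_profile, frac = 0.25) {
  K <- length(r2_profile)
  if (K >= 4L) {
    gain <- diff(r2_profile)  # gain[k-1] = gain of moving to k clusters
    for (k in 3:(K - 1L)) {
      if (gain[k] <= frac * gain[k - 1L] + 1e-12) return(k)
    }
  }
  warning("no elbow found in the R^2 profile; returning k = 1")
  1L
}

#' Bootstrap Jaccard stability of a clustering
#'
#' For each bootstrap resample of the score rows, re-clusters the
#' resample and matches each original cluster to the bootstrap cluster
#' with the highest Jaccard overlap (computed on the set of original
#' points present in the resample). Clusters that routinely dissolve
#' under resampling get low mean Jaccard coefficients.
#'
#' @param scores n x d score matrix
#' @param k number of clusters
#' @param n_resamples bootstrap resamples (at least 20; default 50)
#' @param seed RNG seed
#' @return object of class `cluster_stability`: `per_cluster` mean
#'   Jaccard per original cluster, `mean_jaccard`, `n_resamples`
#' @export
bootstrap_jaccard <- function(scores, k, n_resamples = 50L, seed = 1L) {
  if (n_resamples < 20L) stop("use at least 20 bootstrap resamples")
  scores <- as.matrix(scores)
  n <- nrow(scores)
  set.seed(seed)
  orig <- ward_cluster(scores, k)$labels
  orig_sets <- split(seq_len(n), orig)
  acc <- matrix(NA_real_, n_resamples, length(orig_sets))
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    lab_b <- stats::cutree(stats::hclust(stats::dist(scores[idx, ,
                                                            drop = FALSE]),
                                         method = "ward.D2"), k)
    boot_sets <- lapply(split(seq_along(idx), lab_b),
                        function(ii) unique(idx[ii]))
    for (ci in seq_along(orig_sets)) {
      A <- intersect(orig_sets[[ci]], unique(idx))
      if (length(A) == 0L) next  # cluster absent from this resample
      acc[b, ci] <- max(vapply(boot_sets, function(B)
        length(intersect(A, B)) / length(union(A, B)), numeric(1)))
    }
  }
  if (anyNA(acc))
    warning("some clusters were empty in some resamples and were excluded")
  per <- colMeans(acc, na.rm = TRUE)
  names(per) <- names(orig_sets)
  structure(list(per_cluster = per, mean_jaccard = mean(per),
                 n_resamples = as.integer(n_resamples)),
            class = "cluster_stability")
}

#' @export
print.cluster_stability <- function(x, ...) {
  cat("Bootstrap cluster stability (", x$n_resamples, "resamples ):",
      "mean Jaccard", sprintf("%.3f", x$mean_jaccard), "\n")
  print(round(x$per_cluster, 3))
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of point pairs on which the two partitions agree (same
#' cluster in both, or different cluster in both). [adjusted_rand_index()]
#' is the chance-corrected version.
#'
#' @param a,b cluster label vectors of equal length
#' @return a number in `[0, 1]`
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  (tot + 2 * sum_ij - sum_a - sum_b) / tot
}

#' @rdname rand_index
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(length(a), 2)
  expected <- sum_a * sum_b / tot
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Surrogate decision tree for an MDS-based clustering
#'
#' Fits a depth-limited CART classification tree (Gini impurity)
#' predicting cluster membership from interpretable per-person features,
#' so the clustering can be applied outside the discovery cohort without
#' recomputing dissimilarities. Reports the Rand index between the tree's
#' predictions and the input labels.
#'
#' @param features data frame of interpretable features (e.g. diagnosis
#'   indicators before/after the index diagnosis, ages at first
#'   diagnosis)
#' @param labels cluster labels to emulate
#' @param max_depth tree depth limit (default 4)
#' @return object of class `surrogate_tree`: the fitted `rpart` tree,
#'   `predictions`, `rand_index`
#' @export
surrogate_tree <- function(features, labels, max_depth = 4L) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    warning("labels contain a single class; fitting a trivial tree")
    return(structure(list(tree = NULL,
                          predictions = rep(labels[1], length(labels)),
                          rand_index = 1),
                     class = "surrogate_tree"))
  }
  dat <- cbind(data.frame(.cluster = factor(labels)), features)
  tree <- rpart::rpart(.cluster ~ ., data = dat, method = "class",
                       parms = list(split = "gini"),
                       control = rpart::rpart.control(maxdepth = max_depth,
                                                      cp = 0.001,
                                                      minsplit = 10,
                                                      xval = 0))
  pred <- as.character(stats::predict(tree, type = "class"))
  structure(list(tree = tree, predictions = pred,
                 rand_index = rand_index(pred, as.character(labels))),
            class = "surrogate_tree")
}

#' @export
print.surrogate_tree <- function(x, ...) {
  cat("Surrogate decision tree: Rand index vs input clustering =",
      sprintf("%.3f", x$rand_index), "\n")
  invisible(x)
}

#' Interpretable per-person features for the surrogate tree
#'
#' Diagnosis indicators split into before/after the index diagnosis plus
#' age at first diagnosis per category (NA-free: censoring age is used
#' when a category never occurs).
#'
#' @param cohort a `cohort` object
#' @param group persons to include (default cases)
#' @return data frame, one row per person
#' @export
tree_features <- function(cohort, group = "case") {
  p <- cohort$persons
  if (group != "all") p <- p[p$group == group, , drop = FALSE]
  cats <- cohort$categories
  ev <- cohort$events
  out <- data.frame(row.names = p$person_id)
  censor_age <- as.numeric(p$censor_date - p$birth_date) / DAYS_PER_YEAR
  for (cc in cats) {
    e <- ev[ev$category == cc, ]
    d <- e$first_date[match(p$person_id, e$person_id)]
    age <- as.numeric(d - p$birth_date) / DAYS_PER_YEAR
    before <- !is.na(d) & !is.na(p$scz_first_date) & d <= p$scz_first_date
    after <- !is.na(d) & (is.na(p$scz_first_date) | d > p$scz_first_date)
    out[[paste0(cc, "_before")]] <- as.numeric(before)
    out[[paste0(cc, "_after")]] <- as.numeric(after)
    out[[paste0("age_", cc)]] <- ifelse(is.na(age), censor_age, age)
  }
  out
}

#' Write cluster labels as CSV
#'
#' @param cl a [ward_cluster()] result
#' @param path output file (`person_id,cluster`)
#' @return `path`, invisibly
#' @export
write_clusters <- function(cl, path) {
  utils::write.csv(data.frame(person_id = names(cl$labels),
                              cluster = cl$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
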