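#' Classical (Torgerson) multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared-distance matrix (`B = -1/2 J D^2 J`),
#' eigendecomposes it, and returns scores `X_j = v_j * sqrt(lambda_j)` for
#' the `k` leading positive eigenvalues. Optimal-matching distances are
#' metric but need not be Euclidean, so negative eigenvalues can occur;
#' they are excluded from the scores and from the variance denominator,
#' and their relative mass is reported. The centering statistics (row
#' means and grand mean of `D^2`) are retained so new points can be
#' projected afterwards with [project_new()].
#'
#' Each dimension's sign is fixed by orienting its largest-magnitude
#' loading positive; substantive orientation (e.g. against a comorbidity
#' count) can be applied afterwards with [orient_embedding()].
#'
#' @param D symmetric dissimilarity matrix with zero diagonal
#' @param k number of dimensions to retain (must not exceed the number of
#'   positive eigenvalues)
#' @return an object of class `embedding`: `scores` (n x k),
#'   `eigenvalues` (all, descending), `variance_explained` and
#'   `cum_variance` (fractions of the positive spectrum),
#'   `negative_mass` (|sum of negative eigenvalues| / sum of positive),
#'   `row_means`, `grand_mean`
#' @export
classical_mds <- function(D, k = 3L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric matrix")
  if (max(abs(diag(D))) > 1e-12) stop("D must have a zero diagonal")
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  D2 <- D^2
  rm_ <- rowMeans(D2)
  gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (length(pos) == 0L)
    stop("no positive eigenvalue: the dissimilarity matrix carries no ",
         "usable dimension")
  if (k > length(pos))
    stop("k = ", k, " exceeds the number of positive eigenvalues (usable ",
         "maximum is ", length(pos), ")")
  lam <- e$values[pos[seq_len(k)]]
  V <- e$vectors[, pos[seq_len(k)], drop = FALSE]
  # deterministic sign: largest-|loading| entry of each dimension positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(V, 2, sqrt(lam), `*`)
  colnames(scores) <- paste0("dim", seq_len(k))
  rownames(scores) <- rownames(D)
  pos_sum <- sum(e$values[pos])
  neg_sum <- -sum(e$values[e$values < 0])
  ve <- lam / pos_sum
  structure(list(scores = scores,
                 eigenvalues = e$values,
                 k = k,
                 variance_explained = ve,
                 cum_variance = cumsum(ve),
                 negative_mass = neg_sum / pos_sum,
                 row_means = rm_,
                 grand_mean = gm),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$scores), "points,", x$k,
      "dimensions\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      sprintf("(cumulative %.1f%%)", 100 * x$cum_variance[x$k]), "\n")
  if (x$negative_mass > 0)
    cat(sprintf("  negative eigenvalue mass: %.2f%% of positive spectrum\n",
                100 * x$negative_mass))
  invisible(x)
}

#' Project new points onto an existing MDS solution
#'
#' Gower's add-a-point interpolation: given the distances from a new
#' sequence to every training sequence, the score on dimension `j` is
#' `X_j' (r - d^2) / (2 lambda_j)` with `X_j` the training score column,
#' `r` the row means of the training squared-distance matrix and `d` the
#' new distance vector. Projecting a training point (or an exact
#' duplicate of one) reproduces its training score.
#'
#' @param d_new numeric vector of distances to the training points, or a
#'   matrix with one row per new point
#' @param emb a [classical_mds()] result
#' @return a `k`-vector, or a matrix of scores with one row per new point
#' @export
project_new <- function(d_new, emb) {
  stopifnot(inherits(emb, "embedding"))
  one <- is.null(dim(d_new))
  d_new <- rbind(d_new)
  if (ncol(d_new) != length(emb$row_means))
    stop("distance vector length ", ncol(d_new),
         " does not match the ", length(emb$row_means), " training points")
  lam <- emb$eigenvalues[seq_len(emb$k)]
  b <- sweep(-(d_new^2), 2, emb$row_means, `+`)  # r - d^2, row-wise
  out <- (b %*% emb$scores) %*% diag(1 / (2 * lam), emb$k)
  colnames(out) <- colnames(emb$scores)
  if (one) out[1, ] else out
}

#' Orient MDS dimensions against interpretable features
#'
#' Flips the sign of each dimension whose correlation with the matched
#' feature is negative, so that (for instance) dimension 1 increases with
#' the comorbidity count. Dimensions without a matched feature keep the
#' default largest-loading-positive orientation.
#'
#' @param emb a [classical_mds()] result
#' @param features data frame / matrix with one column per dimension to
#'   orient (column order = dimension order; `NA` columns skipped)
#' @return the embedding with sign-adjusted scores
#' @export
orient_embedding <- function(emb, features) {
  features <- as.data.frame(features)
  for (j in seq_len(min(emb$k, ncol(features)))) {
    f <- features[[j]]
    if (all(is.na(f))) next
    r <- suppressWarnings(stats::cor(emb$scores[, j], as.numeric(f),
                                     use = "complete.obs"))
    if (!is.na(r) && r < 0) emb$scores[, j] <- -emb$scores[, j]
  }
  emb
}

#' Jackknife stability of an MDS configuration
#'
#' Re-embeds the matrix with one point left out (subsampled to
#' `max_leave_out` deletions for large `n`), Procrustes-aligns the
#' reduced solution (rotation, reflection and scaling) to the full
#' solution restricted to the retained points, and summarizes the mean
#' squared aligned displacement relative to the total score variance:
#' `coefficient = 1 - mean displacement / total variance`, clipped at 0.
#' A coefficient near 1 means the configuration barely moves under
#' deletion.
#'
#' @param D symmetric dissimilarity matrix
#' @param k dimensions to embed
#' @param max_leave_out maximum number of leave-one-out deletions
#'   (default 200); deletions are an evenly spaced subsample when
#'   `n > max_leave_out`
#' @return list with `coefficient` (in `[0, 1]`), `n_deletions`
#' @export
jackknife_stability <- function(D, k = 3L, max_leave_out = 200L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 10L) stop("need at least 10 points for a jackknife")
  full <- classical_mds(D, k)
  total_var <- sum(scale(full$scores, scale = FALSE)^2) / n
  if (total_var <= 0) stop("degenerate embedding: zero score variance")
  del <- if (n > max_leave_out)
    unique(round(seq(1, n, length.out = max_leave_out))) else seq_len(n)
  disp <- vapply(del, function(i) {
    sub <- classical_mds(D[-i, -i, drop = FALSE], k)
    aligned <- procrustes_align(sub$scores,
                                full$scores[-i, , drop = FALSE])
    sum((aligned - full$scores[-i, , drop = FALSE])^2) / (n - 1L)
  }, numeric(1))
  list(coefficient = max(0, min(1, 1 - mean(disp) / total_var)),
       n_deletions = length(del))
}

# least-squares Procrustes: rotate/reflect, scale and translate Y onto X
procrustes_align <- function(Y, X) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- sweep(X, 2, cx); B <- sweep(Y, 2, cy)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  scl <- sum(s$d) / sum(B^2)
  sweep(scl * B %*% R, 2, cx, `+`)
}

#' Permutation check of MDS structure
#'
#' A simple reference test of whether the leading eigenstructure exceeds
#' chance: the off-diagonal entries of the dissimilarity matrix are
#' randomly permuted (preserving symmetry), the matrix re-embedded, and
#' the observed cumulative variance of the first `k` dimensions compared
#' with the permuted distribution.
#'
#' @param D symmetric dissimilarity matrix
#' @param k dimensions
#' @param n_perm permutations (default 99)
#' @param seed RNG seed
#' @return list with `p` (permutation p-value) and `observed` cumulative
#'   variance fraction
#' @export
mds_permutation_test <- function(D, k = 3L, n_perm = 99L, seed = 1L) {
  set.seed(seed)
  obs <- classical_mds(D, k)$cum_variance[k]
  n <- nrow(D)
  lower <- which(lower.tri(D))
  stat <- vapply(seq_len(n_perm), function(r) {
    Dp <- matrix(0, n, n)
    Dp[lower] <- sample(D[lower])
    Dp <- Dp + t(Dp)
    tryCatch(classical_mds(Dp, k)$cum_variance[k], error = function(e) NA_real_)
  }, numeric(1))
  stat <- stat[!is.na(stat)]
  list(p = (1 + sum(stat >= obs)) / (1 + length(stat)), observed = obs)
}

#' Post-hoc interpretation of MDS dimensions
#'
#' For each (standardized) dimension, regresses interpretable per-person
#' features on the dimension score: a linear model for numeric features
#' (e.g. total comorbidity count, age at first diagnosis) and a logistic
#' model for binary features (per-diagnosis indicators), reporting the
#' effect per standard-deviation increase of the dimension.
#'
#' @param scores n x k score matrix
#' @param features data frame aligned with the score rows; binary columns
#'   (two distinct non-missing values) are modeled by logistic regression,
#'   the rest linearly
#' @return data frame with `dimension`, `feature`, `type`, `estimate`
#'   (beta, or odds ratio for logistic fits), `ci_low`, `ci_high`, `p`,
#'   and a `separation` flag for logistic fits that did not stabilize
#'   (effect reported as infinite)
#' @export
interpret_dimensions <- function(scores, features) {
  scores <- as.matrix(scores)
  features <- as.data.frame(features)
  if (nrow(features) != nrow(scores))
    stop("features must be aligned with the score rows")
  out <- list()
  for (j in seq_len(ncol(scores))) {
    z <- as.numeric(scale(scores[, j]))
    for (f in names(features)) {
      v <- features[[f]]
      ok <- !is.na(v)
      uv <- unique(v[ok])
      if (length(uv) < 2L) {
        warning("feature '", f, "' is constant; effect reported as NA")
        out[[length(out) + 1L]] <- data.frame(
          dimension = j, feature = f, type = "constant",
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p = NA_real_, separation = FALSE)
        next
      }
      if (length(uv) == 2L) {
        y <- as.numeric(factor(v)) - 1
        fit <- suppressWarnings(
          stats::glm(y ~ z, family = stats::binomial(), subset = ok))
        co <- summary(fit)$coefficients["z", ]
        sep <- abs(co["Estimate"]) > 15 || co["Std. Error"] > 100
        if (sep)
          warning("possible separation for feature '", f,
                  "' on dimension ", j, "; odds ratio reported as infinite")
        est <- if (sep) sign(co["Estimate"]) * Inf else exp(co["Estimate"])
        out[[length(out) + 1L]] <- data.frame(
          dimension = j, feature = f, type = "logistic",
          estimate = unname(est),
          ci_low = unname(exp(co["Estimate"] - 1.96 * co["Std. Error"])),
          ci_high = unname(exp(co["Estimate"] + 1.96 * co["Std. Error"])),
          p = unname(co["Pr(>|z|)"]), separation = sep)
      } else {
        fit <- stats::lm(as.numeric(v) ~ z, subset = ok)
        co <- summary(fit)$coefficients["z", ]
        out[[length(out) + 1L]] <- data.frame(
          dimension = j, feature = f, type = "linear",
          estimate = unname(co["Estimate"]),
          ci_low = unname(co["Estimate"] - 1.96 * co["Std. Error"]),
          ci_high = unname(co["Estimate"] + 1.96 * co["Std. Error"]),
          p = unname(co["Pr(>|t|)"]), separation = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Write MDS scores and an eigenvalue report
#'
#' @param emb a [classical_mds()] result
#' @param scores_path CSV of `person_id,dim1..dimk`
#' @param eigen_path sidecar text report of the eigenspectrum
#' @return `scores_path`, invisibly
#' @export
write_embedding <- function(emb, scores_path, eigen_path = NULL) {
  df <- data.frame(person_id = rownames(emb$scores), emb$scores)
  utils::write.csv(df, scores_path, row.names = FALSE, quote = FALSE)
  if (!is.null(eigen_path)) {
    lines <- c(sprintf("k = %d", emb$k),
               sprintf("variance explained: %s",
                       paste(sprintf("%.4f", emb$variance_explained),
                             collapse = " ")),
               sprintf("cumulative: %s",
                       paste(sprintf("%.4f", emb$cum_variance), collapse = " ")),
               sprintf("negative eigenvalue mass: %.6f", emb$negative_mass),
               "eigenvalues:",
               paste(format(emb$eigenvalues, digits = 8), collapse = " "))
    writeLines(lines, eigen_path)
  }
  invisible(scores_path)
}
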