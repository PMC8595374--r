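#' Joint MANCOVA of MDS dimension scores on one predictor
#'
#' Tests whether a single predictor (one degree of freedom) jointly
#' shifts the score dimensions, using Pillai's trace with its standard F
#' approximation, after adjusting for covariates. Missing predictor or
#' covariate values are removed listwise and the analyzed n reported.
#'
#' @param scores n x k numeric score matrix
#' @param predictor numeric vector, or a two-level factor (coerced to
#'   0/1); must carry one degree of freedom
#' @param covariates optional data frame of adjustment covariates
#'   (typically age at censoring and sex; ancestry components and batch
#'   for genetic-style predictors)
#' @return list with `joint_F`, `joint_p`, `pillai`, `df`,
#'   `n_nonmissing`
#' @export
mancova <- function(scores, predictor, covariates = NULL) {
  scores <- as.matrix(scores)
  x <- one_df_predictor(predictor)
  dat <- assemble_design(scores, x, covariates)
  fit <- stats::lm(dat$Y ~ ., data = dat$X)
  an <- tryCatch(stats::anova(fit, test = "Pillai"),
                 error = function(e) {
                   # an exactly collinear response (perfect association)
                   # leaves rank-deficient residuals; report the limit
                   if (grepl("rank", conditionMessage(e)))
                     return(NULL)
                   stop(e)
                 })
  if (is.null(an))
    return(list(joint_F = Inf, joint_p = 0, pillai = NA_real_,
                df = c(NA_real_, NA_real_), n_nonmissing = nrow(dat$X)))
  row <- an[".pred", ]
  list(joint_F = row[["approx F"]], joint_p = row[["Pr(>F)"]],
       pillai = row[["Pillai"]], df = c(row[["num Df"]], row[["den Df"]]),
       n_nonmissing = nrow(dat$X))
}

one_df_predictor <- function(predictor) {
  if (is.factor(predictor) || is.character(predictor)) {
    predictor <- factor(predictor)
    if (nlevels(predictor) != 2L)
      stop("the predictor must carry one degree of freedom ",
           "(numeric or a two-level factor)")
    predictor <- as.numeric(predictor) - 1
  }
  as.numeric(predictor)
}

# listwise deletion + collinearity check; predictor enters last as .pred
assemble_design <- function(scores, x, covariates) {
  X <- data.frame(.pred = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(x))
    X <- cbind(covariates, X)
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  Y <- scores[keep, , drop = FALSE]
  if (nrow(X) < ncol(X) + ncol(Y) + 2L)
    stop("too few non-missing observations (", nrow(X), ")")
  mm <- stats::model.matrix(~ ., X)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    if (".pred" %in% dropped || sd(X$.pred) == 0)
      stop("constant or collinear predictor: ",
           paste(dropped, collapse = ", "))
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  if (stats::sd(X$.pred) == 0) stop("constant predictor")
  list(Y = Y, X = X)
}

#' Post-hoc per-dimension regressions for a MANCOVA predictor
#'
#' Ordinary least squares of each dimension score on the predictor plus
#' covariates, with the predictor's one-degree-of-freedom ANOVA F test.
#' Intended to be run only for predictors whose joint test passed the
#' multiplicity threshold (the pipeline enforces this; set
#' `force = TRUE` to override).
#'
#' @inheritParams mancova
#' @param joint_p the predictor's joint MANCOVA p-value (checked against
#'   `threshold` unless `force`)
#' @param threshold multiplicity threshold (default 0.002 = 0.05/25)
#' @param force run regardless of the joint test
#' @return data frame with `dimension`, `beta`, `se`, `F`, `p`
#' @export
posthoc_regressions <- function(scores, predictor, covariates = NULL,
                                joint_p = NULL, threshold = 0.002,
                                force = FALSE) {
  if (!force && !is.null(joint_p) && joint_p >= threshold)
    stop("joint test did not pass the threshold (p = ", signif(joint_p, 3),
         "); use force = TRUE to run post-hoc regressions anyway")
  scores <- as.matrix(scores)
  x <- one_df_predictor(predictor)
  dat <- assemble_design(scores, x, covariates)
  out <- lapply(seq_len(ncol(dat$Y)), function(j) {
    fit <- stats::lm(dat$Y[, j] ~ ., data = dat$X)
    co <- summary(fit)$coefficients[".pred", ]
    an <- stats::anova(fit)
    data.frame(dimension = j,
               beta = unname(co["Estimate"]),
               se = unname(co["Std. Error"]),
               F = an[".pred", "F value"],
               p = an[".pred", "Pr(>F)"])
  })
  do.call(rbind, out)
}

#' Multinomial-logit association of cluster membership with a predictor
#'
#' Cluster membership (reference cluster releveled first) is regressed on
#' the predictor plus covariates; reports per-cluster odds ratios versus
#' the reference with Wald p-values. Quasi-separation (a predictor that
#' perfectly identifies a cluster) is flagged.
#'
#' @param labels cluster labels
#' @param predictor numeric or two-level predictor
#' @param covariates optional data frame
#' @param reference reference cluster id (default: largest cluster)
#' @return data frame `cluster`, `or`, `ci_low`, `ci_high`, `p`,
#'   `separation`
#' @export
cluster_association <- function(labels, predictor, covariates = NULL,
                                reference = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need at least two clusters")
  if (is.null(reference))
    reference <- names(sort(table(labels), decreasing = TRUE))[1]
  if (!reference %in% labels) stop("reference cluster not present")
  x <- one_df_predictor(predictor)
  X <- data.frame(.pred = x)
  if (!is.null(covariates)) X <- cbind(as.data.frame(covariates), X)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  y <- stats::relevel(factor(labels[keep]), ref = reference)
  if (stats::sd(X$.pred) == 0) stop("constant predictor")
  fit <- nnet::multinom(y ~ ., data = X, trace = FALSE, maxit = 500)
  co <- stats::coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(co))) {  # two clusters: coef() returns a vector
    co <- matrix(co, 1, dimnames = list(levels(y)[2], names(co)))
    se <- matrix(se, 1, dimnames = dimnames(co))
  }
  beta <- co[, ".pred"]; s <- se[, ".pred"]
  sep <- abs(beta) > 15 | s > 100
  if (any(sep))
    warning("possible separation for cluster(s) ",
            paste(rownames(co)[sep], collapse = ", "))
  z <- beta / s
  data.frame(cluster = rownames(co),
             or = ifelse(sep, sign(beta) * Inf, exp(beta)),
             ci_low = exp(beta - 1.96 * s),
             ci_high = exp(beta + 1.96 * s),
             p = 2 * stats::pnorm(-abs(z)),
             separation = sep,
             row.names = NULL)
}

#' Scan many variables against the MDS dimensions
#'
#' Runs [mancova()] per variable, then [posthoc_regressions()] for the
#' variables passing the Bonferroni threshold, mirroring the usual
#' joint-then-post-hoc association table.
#'
#' @param scores n x k score matrix
#' @param variables data frame, one column per variable to test
#' @param covariates optional data frame of adjustment covariates
#' @param threshold joint-test threshold (default `0.05 /
#'   ncol(variables)`)
#' @return data frame with one row per variable: `variable`, `n`, `F`,
#'   `p`, `significant`, and `beta<j>` / `p<j>` per dimension (NA unless
#'   significant)
#' @export
association_scan <- function(scores, variables, covariates = NULL,
                             threshold = NULL) {
  variables <- as.data.frame(variables)
  if (is.null(threshold)) threshold <- 0.05 / ncol(variables)
  k <- ncol(as.matrix(scores))
  rows <- lapply(names(variables), function(v) {
    res <- tryCatch(mancova(scores, variables[[v]], covariates),
                    error = function(e) NULL)
    row <- data.frame(variable = v,
                      n = if (is.null(res)) NA else res$n_nonmissing,
                      F = if (is.null(res)) NA else res$joint_F,
                      p = if (is.null(res)) NA else res$joint_p,
                      significant = !is.null(res) && res$joint_p < threshold)
    for (j in seq_len(k)) {
      row[[paste0("beta", j)]] <- NA_real_
      row[[paste0("p", j)]] <- NA_real_
    }
    if (row$significant) {
      ph <- posthoc_regressions(scores, variables[[v]], covariates,
                                joint_p = res$joint_p, threshold = threshold)
      for (j in seq_len(k)) {
        row[[paste0("beta", j)]] <- ph$beta[j]
        row[[paste0("p", j)]] <- ph$p[j]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Replication by projection onto the primary cohort's MDS dimensions
#'
#' Computes the primary dissimilarity matrix and embedding, projects each
#' replication sequence onto the primary dimensions via its distances to
#' all primary sequences, reruns the association scan on the replication
#' scores, and reports the sign concordance of the post-hoc coefficients
#' for variables significant in the primary cohort.
#'
#' @param primary_seqset,replication_seqset [build_sequences()] results
#'   on the same alphabet and target length
#' @param primary_variables,replication_variables data frames of
#'   variables to test (same columns)
#' @param primary_covariates,replication_covariates optional adjustment
#'   covariates
#' @param model a [cost_model()]
#' @param k number of MDS dimensions (default 3)
#' @param threshold joint-test threshold
#' @return list with `primary` and `replication` association tables,
#'   `replication_scores`, `concordance` (fraction of primary-significant
#'   variable-dimension coefficients with matching sign) and `embedding`
#' @export
replication_harness <- function(primary_seqset, replication_seqset,
                                primary_variables, replication_variables,
                                primary_covariates = NULL,
                                replication_covariates = NULL,
                                model = cost_model(), k = 3L,
                                threshold = NULL) {
  if (length(replication_seqset$sequences) == 0L)
    stop("empty replication sequence set")
  if (!identical(primary_seqset$alphabet$categories,
                 replication_seqset$alphabet$categories))
    stop("alphabet mismatch between primary and replication cohorts")
  tm <- estimate_transitions(primary_seqset)
  D <- pairwise_matrix(primary_seqset, model, tm)
  emb <- classical_mds(D, k)
  Dx <- cross_distances(replication_seqset, primary_seqset, model, tm)
  rep_scores <- project_new(Dx, emb)
  rownames(rep_scores) <- rownames(Dx)
  prim <- association_scan(emb$scores, primary_variables,
                           primary_covariates, threshold)
  repl <- association_scan(rep_scores, replication_variables,
                           replication_covariates, threshold)
  # concordance is judged over the primary cohort's significant post-hoc
  # coefficients (joint test passed and per-dimension p < 0.05), the
  # coefficients whose sign the primary analysis actually interprets
  bcols <- grep("^beta", names(prim), value = TRUE)
  sig <- which(prim$significant)
  n_tot <- 0L; n_conc <- 0L
  for (i in sig) for (bc in bcols) {
    pc <- sub("^beta", "p", bc)
    bp <- prim[[bc]][i]; br <- repl[[bc]][i]; pp <- prim[[pc]][i]
    if (!is.na(bp) && !is.na(br) && !is.na(pp) && pp < 0.05 && bp != 0) {
      n_tot <- n_tot + 1L
      if (sign(bp) == sign(br)) n_conc <- n_conc + 1L
    }
  }
  list(primary = prim, replication = repl,
       replication_scores = rep_scores,
       concordance = if (n_tot > 0) n_conc / n_tot else NA_real_,
       n_compared = n_tot,
       embedding = emb)
}
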