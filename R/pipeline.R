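#' Configure an end-to-end pipeline run
#'
#' Either point `cohort_dir` at a directory of cohort CSVs (see
#' [read_cohort()]) or leave it `NULL` to simulate a cohort from
#' `sim`. All stage parameters are recorded in the run manifest.
#'
#' @param out_dir output directory
#' @param cohort_dir optional input cohort directory
#' @param sim a [sim_config()] used when `cohort_dir` is `NULL`
#' @param increment grid increment in years
#' @param target_length grid length
#' @param scheme,indel substitution-cost scheme and indel cost
#' @param mds_k MDS dimensions
#' @param cluster_k number of clusters, or `"auto"` for the elbow rule
#' @param n_bootstrap bootstrap resamples for cluster stability
#' @param seed seed for the stochastic stages
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            cohort_dir = NULL,
                            sim = sim_config(n_cases = 200),
                            increment = 1,
                            target_length = 36L,
                            scheme = "paper_overlap",
                            indel = 1.0,
                            mds_k = 3L,
                            cluster_k = "auto",
                            n_bootstrap = 50L,
                            seed = 1L) {
  if (!is.null(cohort_dir) && !dir.exists(cohort_dir))
    stop("cohort directory does not exist: ", cohort_dir)
  if (!is.null(cohort_dir) &&
      !file.exists(file.path(cohort_dir, "events.csv")))
    stop("missing events file: ", file.path(cohort_dir, "events.csv"))
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir, sim = sim,
                 increment = increment,
                 target_length = as.integer(target_length),
                 scheme = scheme, indel = indel, mds_k = as.integer(mds_k),
                 cluster_k = cluster_k,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full trajectory-analysis pipeline
#'
#' Stages, in order: cohort (simulate or load), state sequences,
#' pairwise optimal-matching dissimilarities, classical MDS, Ward
#' clustering with bootstrap stability and a surrogate tree, cumulative
#' incidence / relative risks / pairwise time-dependent Cox hazards, and
#' the covariate association scan. Every artifact is written under
#' `config$out_dir` and checksummed into `manifest.txt` together with the
#' seed and stage parameters; a rerun with the same config reproduces the
#' checksums.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) a list with the in-memory stage results
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("cohort", {
    if (is.null(config$cohort_dir)) {
      co <- simulate_cohort(config$sim, seed = config$seed)
      write_cohort(co, file.path(out, "cohort"))
      co
    } else read_cohort(config$cohort_dir)
  })

  model <- cost_model(config$scheme, config$indel)
  seqset <- stage("sequences", {
    ss <- build_sequences(cohort, increment = config$increment,
                          target_length = config$target_length)
    write_sequences(ss, file.path(out, "sequences.csv"))
    ss
  })

  D <- stage("dissimilarity", {
    D <- pairwise_matrix(seqset, model)
    write_dissimilarity(D, file.path(out, "dissimilarity.tsv"))
    D
  })

  emb <- stage("mds", {
    emb <- classical_mds(D, config$mds_k)
    write_embedding(emb, file.path(out, "scores.csv"),
                    file.path(out, "eigenvalues.txt"))
    emb
  })

  clus <- stage("cluster", {
    probe <- ward_cluster(emb$scores, 2L, k_max = 10L)
    k <- if (identical(config$cluster_k, "auto"))
      select_k_quiet(probe$r2_profile) else as.integer(config$cluster_k)
    k <- max(k, 2L)
    cl <- ward_cluster(emb$scores, k, k_max = 10L)
    write_clusters(cl, file.path(out, "clusters.csv"))
    stab <- bootstrap_jaccard(emb$scores, k,
                              n_resamples = config$n_bootstrap,
                              seed = config$seed)
    utils::write.table(
      data.frame(cluster = names(stab$per_cluster),
                 mean_jaccard = stab$per_cluster),
      file.path(out, "cluster_stability.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    feats <- tree_features(cohort)
    tr <- surrogate_tree(feats[names(cl$labels), , drop = FALSE], cl$labels)
    list(clusters = cl, stability = stab, tree = tr)
  })

  epi <- stage("epi", {
    hz <- pairwise_hazards(cohort)
    utils::write.table(hz, file.path(out, "pairwise_hazards.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    at_age <- min(30, config$target_length * config$increment)
    ci_rows <- lapply(cohort$categories, function(cc) {
      ci <- tryCatch(cumulative_incidence(cohort, cc, at_age,
                                          split_by_index = TRUE),
                     error = function(e) NULL)
      if (is.null(ci)) return(NULL)
      data.frame(category = cc, age = at_age, estimate = ci$estimate,
                 lo = ci$ci_low, hi = ci$ci_high,
                 before_fraction = ci$before_fraction)
    })
    ci_tab <- do.call(rbind, ci_rows)
    utils::write.table(ci_tab, file.path(out, "cumulative_incidence.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(hazards = hz, cumulative_incidence = ci_tab)
  })

  assoc <- stage("assoc", {
    cv <- cohort$covariates
    cases <- cohort$persons$person_id[cohort$persons$group == "case"]
    cv <- cv[match(rownames(emb$scores), cv$person_id), , drop = FALSE]
    p <- cohort$persons[match(rownames(emb$scores),
                              cohort$persons$person_id), ]
    covs <- data.frame(
      age_at_censoring = as.numeric(p$censor_date - p$birth_date) /
        DAYS_PER_YEAR,
      sex = as.integer(p$sex == "M"))
    vars <- cv[, setdiff(names(cv), "person_id"), drop = FALSE]
    tab <- association_scan(emb$scores, vars, covs)
    utils::write.table(tab, file.path(out, "associations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          "manifest.txt"))
    sums <- tools::md5sum(file.path(out, files))
    lines <- c(sprintf("seed: %d", config$seed),
               sprintf("increment: %s", format(config$increment)),
               sprintf("scheme: %s", config$scheme),
               sprintf("indel: %s", format(config$indel)),
               sprintf("mds_k: %d", config$mds_k),
               sprintf("cluster_k: %s", format(config$cluster_k)),
               paste0(files, "  ", unname(sums)))
    writeLines(lines, file.path(out, "manifest.txt"))
    lines
  })

  invisible(list(cohort = cohort, sequences = seqset, D = D,
                 embedding = emb, clustering = clus, epi = epi,
                 associations = assoc, manifest = manifest))
}

select_k_quiet <- function(profile) {
  suppressWarnings(select_k(profile))
}
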