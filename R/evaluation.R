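#' Cross-validation plan over known driver genes
#'
#' Evenly splits the known-driver genes into `k` folds by a seeded
#' shuffle followed by round-robin assignment, so fold sizes differ by at
#' most one and the same seed always yields the same plan.
#'
#' @param drivers character vector of benchmark driver genes.
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return An object of class `"cv_plan"`: list with `k`, `seed` and
#'   `fold_of`, a named integer vector mapping each driver to its fold.
#' @export
cv_plan <- function(drivers, k = 5L, seed = 1L) {
  drivers <- unique(as.character(drivers))
  if (k <= 1L) stop("k must be at least 2")
  if (length(drivers) < k)
    stop("need at least as many driver genes as folds")
  set.seed(as.integer(seed))
  shuffled <- sample(drivers)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)),
                             shuffled)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 fold_of = fold_of), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv plan: %d drivers in %d folds (seed %d); sizes: %s\n",
              length(x$fold_of), x$k, x$seed,
              paste(tabulate(x$fold_of, x$k), collapse = ", ")))
  invisible(x)
}

#' Cross-validated driver discovery
#'
#' For each fold of the plan, the held-out drivers' `is_driver` facts are
#' removed from the graph, an embedding is trained on the remainder, and
#' every gene is scored on `(gene, is_driver, D)`.  Each benchmark
#' driver's reported score comes exclusively from the fold in which its
#' supervision triplet was absent from training; non-benchmark genes
#' (supervision-free in every fold) are scored by all fold models and
#' averaged by default, or taken from the first fold with
#' `negatives_from = "first_fold"`.  The concatenated scores are
#' therefore free of supervision leakage for every evaluated gene.
#'
#' Fold models have unrelated score scales, so by default each fold's
#' scores are converted to within-fold percentiles (a rank transform)
#' before concatenation; `concatenate = "raw"` keeps raw recovery
#' losses.  To damp single-model score noise, each fold trains an
#' `ensemble` of models differing only in training seed (the training
#' graph, and hence the leakage guarantee, is identical within a fold)
#' and fold scores are averaged over the ensemble.
#'
#' @param graph a knowledge graph containing the plan's driver triplets.
#' @param plan a [cv_plan()].
#' @param ... arguments passed to [kge_fit()] (`variant`, `norm`, `dim`,
#'   `epochs`, ...).  The per-fold training seed is `seed + fold`.
#' @param seed base seed for fold training.
#' @param negatives_from `"average"` (default) or `"first_fold"`.
#' @param concatenate `"percentile"` (default) or `"raw"` fold-score
#'   concatenation.
#' @param ensemble models trained per fold (default 3).
#' @param keep_models keep the fitted models in the result.
#' @return An object of class `"kge_cv"`: list with `scores` (data.frame
#'   `gene`, `score`, `label` in `{driver, other}`, `fold`; fold `NA`
#'   for averaged negatives), `plan`, and optionally `models`.
#' @export
cv_driver_discovery <- function(graph, plan, ..., seed = 1L,
                                negatives_from = c("average", "first_fold"),
                                concatenate = c("percentile", "raw"),
                                ensemble = 3L, keep_models = FALSE) {
  stopifnot(inherits(graph, "knowledge_graph"), inherits(plan, "cv_plan"),
            ensemble >= 1L)
  negatives_from <- match.arg(negatives_from)
  concatenate <- match.arg(concatenate)
  bench <- names(plan$fold_of)
  is_dr <- graph$triplets$relation == "is_driver"
  missing_bench <- setdiff(bench, graph$triplets$head[is_dr])
  if (length(missing_bench))
    stop("graph lacks is_driver triplets for plan drivers: ",
         paste(missing_bench, collapse = ", "))
  genes <- graph$entities$id[graph$entities$kind == "gene"]
  ensemble <- as.integer(ensemble)
  n_models <- plan$k * ensemble
  col_of <- function(f, e) (f - 1L) * ensemble + e
  fold_scores <- matrix(NA_real_, length(genes), n_models,
                        dimnames = list(genes, NULL))
  models <- vector("list", n_models)
  for (f in seq_len(plan$k)) {
    held <- bench[plan$fold_of[bench] == f]
    drop <- is_dr & graph$triplets$head %in% held
    train_graph <- assemble_graph(graph$triplets[!drop, , drop = FALSE],
                                  graph$vocab)
    # leakage assertion: no held-out supervision in the training set
    stopifnot(!any(has_triplet(train_graph, held, "is_driver",
                               driver_label_id())))
    for (e in seq_len(ensemble)) {
      fit <- tryCatch(
        kge_fit(train_graph, ...,
                seed = as.integer(seed) + f + 1009L * (e - 1L)),
        error = function(err) stop("training failed in fold ", f, ": ",
                                   conditionMessage(err), call. = FALSE))
      in_model <- genes[genes %in% fit$entities]
      fold_scores[in_model, col_of(f, e)] <- score_triplets(
        fit, new_triplets(in_model, rep("is_driver", length(in_model)),
                          rep(driver_label_id(), length(in_model))))
      if (keep_models) models[[col_of(f, e)]] <- fit
    }
  }
  ok <- rowSums(is.na(fold_scores)) == 0L
  if (any(!ok))
    warning(sum(!ok), " gene(s) not embedded in every fold were dropped")
  fold_scores <- fold_scores[ok, , drop = FALSE]
  if (concatenate == "percentile")
    fold_scores <- apply(fold_scores, 2L, rank) / nrow(fold_scores)
  genes <- rownames(fold_scores)
  score <- numeric(length(genes))
  fold <- rep(NA_integer_, length(genes))
  is_bench <- genes %in% bench
  fold[is_bench] <- plan$fold_of[genes[is_bench]]
  bench_cols <- function(i)
    mean(fold_scores[i, col_of(fold[i], seq_len(ensemble))])
  score[is_bench] <- vapply(which(is_bench), bench_cols, numeric(1))
  if (negatives_from == "average") {
    score[!is_bench] <- rowMeans(fold_scores[!is_bench, , drop = FALSE])
  } else {
    score[!is_bench] <- rowMeans(fold_scores[!is_bench,
                                             col_of(1L, seq_len(ensemble)),
                                             drop = FALSE])
    fold[!is_bench] <- 1L
  }
  out <- list(scores = data.frame(
    gene = genes, score = score,
    label = ifelse(is_bench, "driver", "other"),
    fold = fold, stringsAsFactors = FALSE),
    plan = plan)
  if (keep_models) out$models <- models
  class(out) <- "kge_cv"
  out
}

#' @export
print.kge_cv <- function(x, ...) {
  roc <- roc_auc(stats::setNames(x$scores$score, x$scores$gene),
                 x$scores$gene[x$scores$label == "driver"])
  cat(sprintf("cross-validated driver discovery: %d genes (%d benchmark), AUC %.3f\n",
              nrow(x$scores), sum(x$scores$label == "driver"), roc$auc))
  invisible(x)
}

#' Subtype assignments from cross-validation fold models
#'
#' Averages the `(gene, belongs_to, S)` recovery-loss matrix over the
#' fold models of a [cv_driver_discovery()] run (fitted with
#' `keep_models = TRUE`) and assigns each gene the arg-min subtype.
#' Averaging across folds smooths the per-model noise; subtype
#' supervision is never held out, so no leakage is involved.
#'
#' @param cv a `kge_cv` object carrying `models`.
#' @param genes genes to assign; default all evaluated genes.
#' @return data.frame `gene`, `assigned_subtype`.
#' @export
cv_subtype_assignments <- function(cv, genes = NULL) {
  stopifnot(inherits(cv, "kge_cv"))
  if (is.null(cv$models))
    stop("run cv_driver_discovery() with keep_models = TRUE")
  if (is.null(genes)) genes <- cv$scores$gene
  m1 <- cv$models[[1L]]
  subtypes <- sort_c(m1$entities[m1$ent_kind == "subtype"])
  acc <- matrix(0, length(genes), length(subtypes),
                dimnames = list(genes, subtypes))
  for (m in cv$models)
    acc <- acc + subtype_score_matrix(m, genes, subtypes)
  data.frame(gene = genes,
             assigned_subtype = argmin_subtype(acc / length(cv$models)),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC for driver scores
#'
#' Lower recovery loss means a stronger driver prediction, so the ROC
#' sweep predicts "driver" for all genes with score at or below a moving
#' threshold.  TPR is the fraction of benchmark drivers recovered, FPR
#' the fraction of non-benchmark genes called.  The trapezoidal area
#' under the resulting curve equals the Mann-Whitney statistic
#' `P(score_pos < score_neg) + 0.5 * P(tie)`.
#'
#' @param scores named numeric vector of per-gene scores (lower = more
#'   driver-like).
#' @param positives character vector of benchmark driver genes; must be
#'   a subset of `names(scores)`.
#' @return An object of class `"roc_result"`: list with `points` (a
#'   data.frame of `fpr`, `tpr`, starting at (0,0) and ending at (1,1))
#'   and `auc` (trapezoidal area).
#' @export
roc_auc <- function(scores, positives) {
  stopifnot(!is.null(names(scores)), all(positives %in% names(scores)))
  lab <- names(scores) %in% positives
  P <- sum(lab); N <- sum(!lab)
  if (P == 0L || N == 0L)
    stop("need at least one positive and one negative gene")
  o <- order(scores, method = "radix")
  s <- scores[o]; l <- lab[o]
  last <- which(!duplicated(s, fromLast = TRUE))  # threshold group ends
  tpr <- c(0, cumsum(l)[last] / P)
  fpr <- c(0, cumsum(!l)[last] / N)
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlab = "FPR", ylab = "TPR",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write the cross-validation report
#'
#' Emits the per-gene score table (TSV), the ROC points (CSV) and a
#' one-paragraph summary with the AUC.
#'
#' @param cv a [cv_driver_discovery()] result.
#' @param dir output directory (created if needed).
#' @return The AUC, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cv$scores[order(cv$scores$score, cv$scores$gene,
                        method = "radix"), ]
  sc$score <- sprintf("%.10g", sc$score)
  write.table(sc, file.path(dir, "cv_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  roc <- roc_auc(stats::setNames(cv$scores$score, cv$scores$gene),
                 cv$scores$gene[cv$scores$label == "driver"])
  pts <- roc$points
  pts[] <- lapply(pts, function(x) sprintf("%.10g", x))
  write.table(pts, file.path(dir, "roc_points.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  writeLines(sprintf(
    "folds: %d\nbenchmark drivers: %d\nevaluated genes: %d\nAUC: %.6f",
    cv$plan$k, sum(cv$scores$label == "driver"), nrow(cv$scores),
    roc$auc), file.path(dir, "cv_summary.txt"))
  invisible(roc$auc)
}
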