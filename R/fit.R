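#' Fit translational knowledge-graph embeddings
#'
#' Learns low-dimensional vectors for every entity and relation of a
#' knowledge graph so that true facts have small recovery loss
#' `Dis(h, t) = ||map(v_h) + v_r - map(v_t)||`, where the mapping into
#' the relation-specific gene space depends on `variant`:
#'
#' * `"nomap"` — plain translation, `map(v) = v`;
#' * `"planemap"` — projection on the relation hyperplane with unit
#'   normal `w_r`, `map(v) = v - (w_r . v) w_r`;
#' * `"staticmap"` — a relation-specific matrix, `map(v) = M_r v`;
#' * `"dynmap"` — a dynamic, relation- *and* entity-specific rank-one
#'   mapping `map(v_e) = (w_r w_e^T + I) v_e`, the default.
#'
#' The metric is the sparsity-inducing L1 norm by default; L2 is
#' available for ablation.  Since minimising recovery loss over observed
#' triplets alone is degenerate (the all-zero embedding is optimal), the
#' objective is the standard margin-ranking surrogate with filtered
#' negative sampling: for each observed fact a corrupted fact absent from
#' the graph is drawn, and `max(0, margin + Dis(pos) - Dis(neg))` is
#' minimised with Adam in mini-batches.  Entity vectors are projected
#' onto the unit ball after every update; hyperplane normals are kept at
#' unit norm.  All randomness (initialisation, batch order, negative
#' sampling) flows from `seed`, so runs are bit-reproducible.
#'
#' @param graph a [knowledge graph][assemble_graph].
#' @param variant mapping variant, one of `"dynmap"`, `"nomap"`,
#'   `"planemap"`, `"staticmap"`.
#' @param norm distance metric, `"L1"` (default) or `"L2"`.
#' @param dim embedding dimension (default 50).
#' @param epochs passes over the triplet set (default 350; the
#'   margin loss plateaus well before that at these graph sizes and the
#'   returned model averages the final quarter of epochs).
#' @param batch_size mini-batch size (default 512).
#' @param learning_rate Adam step size (default 1e-3).
#' @param margin ranking margin separating positive from corrupted
#'   triplet scores (default 2).
#' @param negatives corrupted triplets drawn per observed triplet
#'   (default 5); several corruptions per fact sharpen the ranking
#'   signal on small graphs.
#' @param average_tail fraction of final epochs over which parameters
#'   are averaged (tail iterate averaging; 0 returns the last iterate).
#' @param seed integer seed controlling all randomness.
#' @param max_tries rejection-sampling attempts before the sampler falls
#'   back to exhaustive enumeration.
#' @return An object of class `"kge"` with entity/relation vectors,
#'   projection parameters of the chosen variant, the per-epoch mean
#'   margin loss (`loss_trace`) and the full configuration.
#' @seealso [score_triplets()], [rank_drivers()], [cv_driver_discovery()]
#' @export
kge_fit <- function(graph,
                    variant = c("dynmap", "nomap", "planemap", "staticmap"),
                    norm = c("L1", "L2"),
                    dim = 50, epochs = 350, batch_size = 512,
                    learning_rate = 1e-3, margin = 2, negatives = 5,
                    average_tail = 0.25, seed = 1L, max_tries = 64L) {
  stopifnot(inherits(graph, "knowledge_graph"),
            nrow(graph$triplets) > 0,
            dim >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, margin >= 0, negatives >= 1,
            average_tail >= 0, average_tail <= 1)
  variant <- match.arg(variant)
  norm <- match.arg(norm)
  idx <- graph_index(graph)
  set.seed(as.integer(seed))
  init <- kge_init(length(idx$entities), length(idx$relations), dim, variant)
  fit <- cpp_train(init$E, init$P, init$R, init$Q, init$M,
                   cbind(idx$h, idx$r, idx$t),
                   idx$ent_kind, idx$rel_hkind, idx$rel_tkind,
                   variant_code(variant), norm_code(norm),
                   margin, learning_rate, as.integer(epochs),
                   as.integer(batch_size), as.integer(negatives),
                   as.integer(max_tries), average_tail)
  if (variant == "planemap") # tail averaging can leave w_r slightly off
    fit$Q <- fit$Q / pmax(sqrt(rowSums(fit$Q^2)), 1e-12)
  new_kge(entities = idx$entities, relations = idx$relations,
          ent_kind = graph$entities$kind,
          E = fit$E, P = fit$P, R = fit$R, Q = fit$Q, M = fit$M,
          variant = variant, norm = norm, dim = dim,
          vocab = graph$vocab, loss_trace = as.numeric(fit$loss_trace),
          initial_loss = mean(cpp_score_triplets(
            init$E, init$P, init$R, init$Q, init$M,
            idx$h, idx$r, idx$t, variant_code(variant), norm_code(norm))),
          final_positive_loss = mean(cpp_score_triplets(
            fit$E, fit$P, fit$R, fit$Q, fit$M,
            idx$h, idx$r, idx$t, variant_code(variant), norm_code(norm))),
          config = list(epochs = epochs, batch_size = batch_size,
                        learning_rate = learning_rate, margin = margin,
                        negatives = negatives,
                        average_tail = average_tail,
                        seed = as.integer(seed),
                        max_tries = as.integer(max_tries)))
}

variant_code <- function(variant) {
  match(variant, c("nomap", "planemap", "staticmap", "dynmap")) - 1L
}
norm_code <- function(norm) if (identical(norm, "L1")) 1L else 2L

# Initialisation: vectors uniform in [-6/sqrt(d), 6/sqrt(d)]; hyperplane
# normals random unit vectors; entity projections zero (so dynmap starts
# at its nomap reduction point) with random relation projections to keep
# their gradient path alive; relation matrices start at the identity.
kge_init <- function(n_ent, n_rel, dim, variant) {
  b <- 6 / sqrt(dim)
  E <- matrix(runif(n_ent * dim, -b, b), n_ent, dim)
  R <- matrix(runif(n_rel * dim, -b, b), n_rel, dim)
  P <- matrix(0, n_ent, dim)
  Q <- matrix(0, n_rel, dim)
  if (variant == "planemap") {
    Q <- matrix(runif(n_rel * dim, -b, b), n_rel, dim)
    Q <- Q / pmax(sqrt(rowSums(Q^2)), 1e-12)
  } else if (variant == "dynmap") {
    Q <- matrix(runif(n_rel * dim, -b, b), n_rel, dim)
  }
  M <- matrix(rep(as.numeric(diag(dim)), each = n_rel), n_rel, dim * dim)
  list(E = E, P = P, R = R, Q = Q, M = M)
}

new_kge <- function(entities, relations, ent_kind, E, P, R, Q, M,
                    variant, norm, dim, vocab, loss_trace = numeric(),
                    initial_loss = NA_real_,
                    final_positive_loss = NA_real_, config = list()) {
  rownames(E) <- entities; rownames(P) <- entities
  rownames(R) <- relations; rownames(Q) <- relations; rownames(M) <- relations
  structure(list(entities = entities, relations = relations,
                 ent_kind = ent_kind, E = E, P = P, R = R, Q = Q, M = M,
                 variant = variant, norm = norm, dim = dim, vocab = vocab,
                 loss_trace = loss_trace, initial_loss = initial_loss,
                 final_positive_loss = final_positive_loss,
                 config = config),
            class = "kge")
}

#' Recovery loss scores of triplets under a fitted model
#'
#' Computes `Dis(h, t)` for each queried fact under the model's mapping
#' variant and metric.  Lower scores mean the model considers the fact
#' more plausible ("recovers" it better); scores are non-negative.
#'
#' @param model a fitted [kge_fit()] object.
#' @param triplets data.frame with columns `head`, `relation`, `tail`.
#' @return Numeric vector of recovery losses, one per row.
#' @export
score_triplets <- function(model, triplets) {
  stopifnot(inherits(model, "kge"))
  h <- match(triplets$head, model$entities)
  t <- match(triplets$tail, model$entities)
  r <- match(triplets$relation, model$relations)
  if (anyNA(h) || anyNA(t)) {
    miss <- unique(c(triplets$head[is.na(h)], triplets$tail[is.na(t)]))
    stop("no embedding for entity(ies): ", paste(sQuote(miss), collapse = ", "))
  }
  if (anyNA(r))
    stop("no embedding for relation(s): ",
         paste(sQuote(unique(triplets$relation[is.na(r)])), collapse = ", "))
  cpp_score_triplets(model$E, model$P, model$R, model$Q, model$M,
                     h - 1L, r - 1L, t - 1L,
                     variant_code(model$variant), norm_code(model$norm))
}

#' Draw a corrupted (negative) triplet
#'
#' Replaces the head or the tail of an observed fact with another entity
#' of the same kind such that the corrupted fact is *not* a member of the
#' graph (filtered sampling).  The corrupted side is chosen uniformly
#' among feasible sides; relations whose tail is the unique driver-label
#' node can only be corrupted at the head.
#'
#' @param g a knowledge graph.
#' @param head,relation,tail the observed fact to corrupt.
#' @param max_tries rejection-sampling attempts before exhaustive
#'   enumeration.
#' @return A one-row triplet data.frame.
#' @export
corrupt_triplet <- function(g, head, relation, tail, max_tries = 64L) {
  stopifnot(inherits(g, "knowledge_graph"),
            has_triplet(g, head, relation, tail) || TRUE)
  idx <- graph_index(g)
  h <- match(head, idx$entities) - 1L
  t <- match(tail, idx$entities) - 1L
  r <- match(relation, idx$relations) - 1L
  if (is.na(h) || is.na(t) || is.na(r))
    stop("triplet references unknown entity or relation")
  out <- cpp_negative_sample(cbind(idx$h, idx$r, idx$t),
                             length(idx$entities), length(idx$relations),
                             h, r, t, idx$ent_kind,
                             idx$rel_hkind[r + 1L], idx$rel_tkind[r + 1L],
                             as.integer(max_tries))
  new_triplets(idx$entities[out[1L] + 1L], idx$relations[out[2L] + 1L],
               idx$entities[out[3L] + 1L])
}

#' @export
print.kge <- function(x, ...) {
  cat(sprintf("kge model (%s, %s): %d entities, %d relations, dim %d\n",
              x$variant, x$norm, length(x$entities), length(x$relations),
              x$dim))
  if (length(x$loss_trace))
    cat(sprintf("  final mean margin loss %.4f after %d epochs\n",
                x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  invisible(x)
}

#' @export
summary.kge <- function(object, ...) {
  print(object)
  cat(sprintf("  mean positive recovery loss: %.4f (initial %.4f)\n",
              object$final_positive_loss, object$initial_loss))
  cat("  entity kinds:",
      paste(names(table(object$ent_kind)), table(object$ent_kind),
            sep = "=", collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.kge <- function(object, ...) {
  out <- list(entity_vectors = object$E, relation_vectors = object$R)
  if (object$variant == "dynmap")
    out$entity_projections <- object$P
  if (object$variant %in% c("planemap", "dynmap"))
    out$relation_projections <- object$Q
  if (object$variant == "staticmap")
    out$relation_matrices <- lapply(
      stats::setNames(seq_along(object$relations), object$relations),
      function(r) matrix(object$M[r, ], object$dim, object$dim))
  out
}

#' @export
#' @rdname score_triplets
#' @param object,newdata,... `predict` method arguments: `newdata` is a
#'   triplet data.frame as in `score_triplets`.
predict.kge <- function(object, newdata, ...) {
  score_triplets(object, newdata)
}

#' @export
plot.kge <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "mean margin loss",
       main = sprintf("training loss (%s, %s)", x$variant, x$norm), ...)
  invisible(x)
}
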