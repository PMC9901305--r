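#' Assemble a knowledge graph from triplet sets
#'
#' Takes the union of one or more triplet sets (data.frames from the
#' `build_*_triplets()` family), derives the typed entity set from the
#' triplet endpoints, and validates the schema: every relation must be in
#' the vocabulary, and every identifier must be used with a single entity
#' kind (an identifier appearing both as a sample and as a gene is a hard
#' error, not silently namespaced).
#'
#' @param triplet_sets a single triplet data.frame or a list of them.
#' @param vocab relation vocabulary.
#' @return An object of class `"knowledge_graph"`: a list with
#'   `triplets` (deduplicated, lexicographically sorted data.frame),
#'   `entities` (data.frame `id`, `kind`) and `vocab`.
#' @examples
#' g <- assemble_graph(list(
#'   build_driver_triplets(c("TP53", "PIK3CA")),
#'   build_interaction_triplets(data.frame(a = "TP53", b = "PIK3CA"))
#' ))
#' summary(g)
#' @export
assemble_graph <- function(triplet_sets, vocab = relation_vocabulary()) {
  if (is.data.frame(triplet_sets)) triplet_sets <- list(triplet_sets)
  tr <- unique(do.call(rbind, c(triplet_sets,
                                list(new_triplets()))))
  tr <- tr[order(tr$head, tr$relation, tr$tail,
                 method = "radix"), , drop = FALSE]
  rownames(tr) <- NULL

  kinds <- relation_kind_table(vocab)
  unknown <- setdiff(unique(tr$relation), kinds$relation)
  if (length(unknown))
    stop("relation(s) not in vocabulary: ",
         paste(sQuote(unknown), collapse = ", "))
  idx <- match(tr$relation, kinds$relation)
  ent <- unique(data.frame(
    id = c(tr$head, tr$tail),
    kind = c(kinds$head_kind[idx], kinds$tail_kind[idx]),
    stringsAsFactors = FALSE
  ))
  clash <- unique(ent$id[duplicated(ent$id)])
  if (length(clash))
    stop("identifier(s) used with conflicting entity kinds: ",
         paste(sQuote(clash), collapse = ", "))
  sub_ent <- ent$id[ent$kind == "subtype"]
  bad_sub <- setdiff(sub_ent, vocab$subtypes)
  if (length(bad_sub))
    stop("subtype entity outside configured vocabulary: ",
         paste(sQuote(bad_sub), collapse = ", "))
  ent <- ent[order(ent$id, method = "radix"), , drop = FALSE]
  rownames(ent) <- NULL
  structure(list(triplets = tr, entities = ent, vocab = vocab),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge graph:", nrow(x$triplets), "triplets,",
      nrow(x$entities), "entities,",
      length(unique(x$triplets$relation)), "relations in use\n")
  invisible(x)
}

#' @export
summary.knowledge_graph <- function(object, ...) {
  kt <- table(object$entities$kind)
  rt <- table(object$triplets$relation)
  cat("knowledge graph\n")
  cat("  entities:", paste(names(kt), kt, sep = "=", collapse = ", "), "\n")
  cat("  triplets:", nrow(object$triplets), "over",
      length(rt), "relations\n")
  invisible(list(entity_kinds = kt, relation_counts = rt))
}

#' Membership test for a triplet
#'
#' @param g a knowledge graph.
#' @param head,relation,tail components of the queried fact.
#' @return `TRUE` if `(head, relation, tail)` is a fact of `g`.
#' @export
has_triplet <- function(g, head, relation, tail) {
  paste(head, relation, tail, sep = "\r") %in% triplet_key(g$triplets)
}

#' Ablation: confuse all aberration types into one relation
#'
#' Renames every DNA- and RNA-aberration relation to the single relation
#' `"aberration"`, collapsing duplicates created by the merge.  The graph
#' then records only *whether* a gene is aberrant in a sample, not which
#' type of aberration occurred; interactions, synonyms, subtype and
#' driver facts are untouched.  Idempotent.
#'
#' @param g a knowledge graph.
#' @return The ablated knowledge graph.
#' @export
ablate_confuse_types <- function(g) {
  ab <- c(aberration_relations(g$vocab), g$vocab$confused)
  tr <- g$triplets
  tr$relation[tr$relation %in% ab] <- g$vocab$confused
  assemble_graph(tr, g$vocab)
}

#' Ablation: remove gene-gene interaction triplets
#'
#' Drops all `interaction` facts; entities left without any incident
#' triplet disappear from the entity set.  Idempotent.
#'
#' @param g a knowledge graph.
#' @return The ablated knowledge graph.
#' @export
ablate_remove_interactions <- function(g) {
  assemble_graph(g$triplets[g$triplets$relation != "interaction", ,
                            drop = FALSE], g$vocab)
}

# integer-encoded view used by the embedding core: 0-based entity and
# relation indices plus kind codes
graph_index <- function(g) {
  ent <- g$entities$id
  kind <- g$entities$kind
  kt <- relation_kind_table(g$vocab)
  rel <- kt$relation
  list(
    entities = ent,
    relations = rel,
    ent_kind = unname(.kinds[kind]) - 1L,
    rel_hkind = unname(.kinds[kt$head_kind]) - 1L,
    rel_tkind = unname(.kinds[kt$tail_kind]) - 1L,
    h = match(g$triplets$head, ent) - 1L,
    r = match(g$triplets$relation, rel) - 1L,
    t = match(g$triplets$tail, ent) - 1L
  )
}
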