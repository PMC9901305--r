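# Shared in-code fixtures: a tiny hand-built graph with every relation
# category, and a hand-built embedding model whose scores can be worked
# out by hand.

toy_graph <- function() {
  vocab <- relation_vocabulary(subtypes = c("A", "B"))
  assemble_graph(list(
    build_aberration_triplets(data.frame(
      sample_id = c("S1", "S1", "S2", "S3"),
      gene_symbol = c("G1", "G2", "G1", "G3"),
      variant_classification = c("missense mutation", "silent",
                                 "nonsense mutation", "missense mutation"),
      stringsAsFactors = FALSE), vocab),
    kgdriver:::new_triplets(c("S1", "S2"), "over_expression",
                            c("G1", "G3")),
    build_interaction_triplets(data.frame(a = c("G1", "G2"),
                                          b = c("G2", "G3"))),
    build_subtype_triplets(data.frame(
      sample_id = c("S1", "S2", "S3"),
      subtype = c("A", "A", "B"), stringsAsFactors = FALSE), vocab),
    build_driver_triplets(c("G1", "G2"))
  ), vocab)
}

# model with chosen vectors; defaults give a 2-d nomap state
manual_model <- function(E, P = NULL, R, Q = NULL, M = NULL,
                         entities, relations, ent_kind,
                         variant = "nomap", norm = "L1",
                         vocab = relation_vocabulary()) {
  d <- ncol(E)
  if (is.null(P)) P <- matrix(0, nrow(E), d)
  if (is.null(Q)) Q <- matrix(0, nrow(R), d)
  if (is.null(M)) M <- matrix(rep(as.numeric(diag(d)), each = nrow(R)),
                              nrow(R), d * d)
  kgdriver:::new_kge(entities = entities, relations = relations,
                     ent_kind = ent_kind, E = E, P = P, R = R, Q = Q,
                     M = M, variant = variant, norm = norm, dim = d,
                     vocab = vocab)
}

# brute-force Mann-Whitney AUC: every (positive, negative) pair compared,
# ties counted one half (independent of the ROC sweep implementation)
pairwise_auc <- function(scores, positives) {
  pos <- scores[names(scores) %in% positives]
  neg <- scores[!names(scores) %in% positives]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p < q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

small_cohort_params <- function(seed = 7L)
  sim_params(n_samples = 40L, n_genes = 60L, n_drivers = 8L,
             n_subtypes = 3L, seed = seed)
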