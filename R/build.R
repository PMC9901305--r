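# Triplet construction ("splicing"): each builder turns one input table
# into a deduplicated set of (head, relation, tail) facts, represented as
# a character data.frame.  Sets use value semantics: duplicates collapse,
# order is canonicalised at serialization time.

new_triplets <- function(head = character(), relation = character(),
                         tail = character()) {
  df <- data.frame(head = as.character(head),
                   relation = as.character(relation),
                   tail = as.character(tail), stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

triplet_key <- function(tr) paste(tr$head, tr$relation, tr$tail, sep = "\r")

# undirected pair canonicalization: lexicographically smaller endpoint
# first; self-loops dropped
canonical_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  h <- ifelse(swap, b, a)
  t <- ifelse(swap, a, b)
  keep <- h != t
  list(head = h[keep], tail = t[keep])
}

#' Build DNA aberration triplets from a mutation table
#'
#' Each distinct `(sample, gene, variant_class)` row becomes one fact
#' `(sample, variant_class, gene)`: the variant class acts as the
#' relation, so different aberration types stay distinguishable in the
#' graph.
#'
#' @param mutations data.frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification` (values from the 17-class DNA vocabulary).
#' @param vocab relation vocabulary, see [relation_vocabulary()].
#' @return Triplet data.frame (`head`, `relation`, `tail`).
#' @examples
#' m <- data.frame(sample_id = "S1", gene_symbol = "TP53",
#'                 variant_classification = "missense mutation")
#' build_aberration_triplets(m)
#' @export
build_aberration_triplets <- function(mutations,
                                      vocab = relation_vocabulary()) {
  cols <- c("sample_id", "gene_symbol", "variant_classification")
  stopifnot(all(cols %in% names(mutations)))
  if (nrow(mutations) == 0L) {
    warning("empty mutation table: no aberration triplets built")
    return(new_triplets())
  }
  if (any(!nzchar(mutations$sample_id)) || any(!nzchar(mutations$gene_symbol)))
    stop("mutation table contains empty sample or gene identifiers")
  bad <- setdiff(unique(mutations$variant_classification), vocab$dna_types)
  if (length(bad))
    stop("unknown variant classification(s): ",
         paste(sQuote(bad), collapse = ", "))
  new_triplets(mutations$sample_id, mutations$variant_classification,
               mutations$gene_symbol)
}

#' Call RNA over-/under-expression aberrations from an expression matrix
#'
#' Per gene, a robust z-score is computed across the cohort,
#' `z = (x - median) / (1.4826 * MAD)`; samples with `z >= z_threshold`
#' yield `(sample, over_expression, gene)` facts and samples with
#' `z <= -z_threshold` yield `(sample, under_expression, gene)` facts.
#' Genes with fewer than 3 samples or zero MAD are skipped with a message.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param z_threshold positive robust z cutoff (default 2).
#' @return Triplet data.frame.
#' @export
call_rna_aberrations <- function(expr, z_threshold = 2) {
  stopifnot(is.matrix(expr), z_threshold > 0,
            !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (ncol(expr) < 3L) {
    message("fewer than 3 samples: no RNA aberrations called")
    return(new_triplets())
  }
  med <- apply(expr, 1L, stats::median)
  mad_ <- apply(expr, 1L, stats::mad)  # already scaled by 1.4826
  usable <- mad_ > 0
  if (any(!usable))
    message(sum(!usable), " gene(s) with zero MAD skipped")
  if (!any(usable)) return(new_triplets())
  z <- (expr[usable, , drop = FALSE] - med[usable]) / mad_[usable]
  over <- which(z >= z_threshold, arr.ind = TRUE)
  under <- which(z <= -z_threshold, arr.ind = TRUE)
  g <- rownames(z); s <- colnames(z)
  new_triplets(
    head = c(s[over[, 2L]], s[under[, 2L]]),
    relation = rep(c("over_expression", "under_expression"),
                   c(nrow(over), nrow(under))),
    tail = c(g[over[, 1L]], g[under[, 1L]])
  )
}

#' Build gene-gene interaction triplets
#'
#' Interactions are undirected facts; each pair is canonicalised with the
#' lexicographically smaller gene first and stored once as
#' `(gene1, interaction, gene2)`.  Self-loops are dropped.
#'
#' @param edges data.frame whose first two columns are gene symbols.
#' @return Triplet data.frame.
#' @export
build_interaction_triplets <- function(edges) {
  build_pair_triplets(edges, "interaction")
}

#' Build gene synonym triplets
#'
#' Same canonicalization as [build_interaction_triplets()]; synonymous
#' gene names are kept as distinct entities linked by a `synonym`
#' relation, not merged.
#'
#' @inheritParams build_interaction_triplets
#' @param pairs data.frame whose first two columns are gene names.
#' @return Triplet data.frame.
#' @export
build_synonym_triplets <- function(pairs) {
  build_pair_triplets(pairs, "synonym")
}

build_pair_triplets <- function(tab, relation) {
  stopifnot(ncol(tab) >= 2L)
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  bad <- which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))
  if (length(bad))
    stop("malformed ", relation, " rows (empty gene symbol) at line(s): ",
         paste(bad, collapse = ", "))
  p <- canonical_pairs(a, b)
  new_triplets(p$head, rep(relation, length(p$head)), p$tail)
}

#' Build sample-to-subtype annotation triplets
#'
#' @param annotations data.frame with columns `sample_id`, `subtype`.
#' @param vocab relation vocabulary carrying the admissible subtype
#'   labels.
#' @return Triplet data.frame of `(sample, belongs_to, subtype)` facts,
#'   one per sample.
#' @export
build_subtype_triplets <- function(annotations,
                                   vocab = relation_vocabulary()) {
  stopifnot(all(c("sample_id", "subtype") %in% names(annotations)))
  ann <- unique(annotations[c("sample_id", "subtype")])
  bad <- setdiff(unique(ann$subtype), vocab$subtypes)
  if (length(bad))
    stop("unknown subtype label(s): ", paste(sQuote(bad), collapse = ", "))
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup))
    stop("conflicting subtype annotations for sample(s): ",
         paste(dup, collapse = ", "))
  new_triplets(ann$sample_id, rep("belongs_to", nrow(ann)), ann$subtype)
}

#' Build known-driver supervision triplets
#'
#' Every known driver gene is linked to the single driver-label node by a
#' fact `(gene, is_driver, D)`.
#'
#' @param drivers character vector of driver gene symbols.
#' @return Triplet data.frame.
#' @export
build_driver_triplets <- function(drivers) {
  drivers <- unique(as.character(drivers))
  drivers <- drivers[nzchar(drivers)]
  new_triplets(drivers, rep("is_driver", length(drivers)),
               rep(driver_label_id(), length(drivers)))
}
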