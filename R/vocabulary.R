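#' Relation vocabulary of the aberration knowledge graph
#'
#' The graph uses a fixed vocabulary of relations grouped into three
#' disjoint categories: 17 DNA variant classes (a restricted MAF
#' `Variant_Classification` dialect), 2 RNA expression aberrations, and 4
#' structural relations connecting samples, genes, subtypes and the single
#' driver-label node.  The ablation operator [ablate_confuse_types()]
#' additionally introduces the merged relation `"aberration"`.
#'
#' @param subtypes character vector of admissible subtype labels; the
#'   default is the five intrinsic breast-cancer subtypes.
#' @return A list with components `dna_types`, `rna_types`, `structural`,
#'   `confused` (the merged aberration relation name) and `subtypes`,
#'   of class `"relation_vocabulary"`.
#' @examples
#' v <- relation_vocabulary()
#' length(v$dna_types)  # 17
#' @export
relation_vocabulary <- function(subtypes = c("Luminal A", "Luminal B",
                                             "HER2-enriched",
                                             "Triple-negative",
                                             "Normal-like")) {
  v <- list(
    dna_types = c("3' Flank", "3' UTR", "5' Flank", "5' UTR",
                  "frame shift del", "frame shift ins", "IGR",
                  "in frame del", "in frame ins", "intron",
                  "missense mutation", "nonsense mutation",
                  "nonstop mutation", "silent", "splice region",
                  "splice site", "translation start site"),
    rna_types = c("over_expression", "under_expression"),
    structural = c("interaction", "synonym", "belongs_to", "is_driver"),
    confused = "aberration",
    subtypes = subtypes
  )
  stopifnot(!anyDuplicated(c(v$dna_types, v$rna_types, v$structural,
                             v$confused)))
  class(v) <- "relation_vocabulary"
  v
}

#' @rdname relation_vocabulary
#' @param vocab a `relation_vocabulary`.
#' @return `aberration_relations()`: the DNA and RNA relation names (the
#'   relations merged by type confusion).
#' @export
aberration_relations <- function(vocab = relation_vocabulary()) {
  c(vocab$dna_types, vocab$rna_types)
}

# Entity-kind codes shared with the C++ core (0-based there).
.kinds <- c(sample = 1L, gene = 2L, subtype = 3L, driver_label = 4L)

#' The single driver-label sink node
#'
#' All `(gene, is_driver, .)` triplets point at one shared entity,
#' representing "being a cancer driver".
#' @return Its identifier, `"D"`.
#' @export
driver_label_id <- function() "D"

# head/tail entity kinds per relation; confused "aberration" behaves like
# any other sample -> gene aberration relation.
relation_kind_table <- function(vocab = relation_vocabulary()) {
  rel <- c(aberration_relations(vocab), vocab$confused,
           "interaction", "synonym", "belongs_to", "is_driver")
  nab <- length(aberration_relations(vocab)) + 1L
  data.frame(
    relation = rel,
    head_kind = c(rep("sample", nab), "gene", "gene", "sample", "gene"),
    tail_kind = c(rep("gene", nab), "gene", "gene", "subtype",
                  "driver_label"),
    stringsAsFactors = FALSE
  )
}
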