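#' Rank candidate driver genes by is-driver recovery loss
#'
#' Scores the fact `(gene, is_driver, D)` for every candidate gene under
#' a fitted embedding model and sorts ascending: genes whose is-driver
#' fact is recovered with small translational distance are the strongest
#' driver candidates.  Each gene also receives the subtype minimising its
#' `(gene, belongs_to, S)` recovery loss (see [assign_subtype()]).
#'
#' @param model a fitted [kge_fit()] object.
#' @param genes candidate gene identifiers; default every gene-kind
#'   entity in the model.
#' @param subtypes subtype labels to score for assignment; default all
#'   subtype entities of the model (set `character()` to skip
#'   assignment).
#' @return A data.frame of class `"driver_ranking"` with columns `rank`,
#'   `gene`, `driver_score`, `assigned_subtype`, then one score column
#'   per subtype.  Ties in `driver_score` are broken lexicographically
#'   by gene identifier; ranks are `1..N`.
#' @export
rank_drivers <- function(model, genes = NULL, subtypes = NULL) {
  stopifnot(inherits(model, "kge"))
  if (is.null(genes)) genes <- model$entities[model$ent_kind == "gene"]
  if (length(genes) == 0L)
    return(structure(data.frame(rank = integer(), gene = character(),
                                driver_score = numeric(),
                                assigned_subtype = character(),
                                stringsAsFactors = FALSE),
                     class = c("driver_ranking", "data.frame")))
  if (is.null(subtypes))
    subtypes <- sort_c(model$entities[model$ent_kind == "subtype"])
  sc <- score_triplets(model, new_triplets(
    genes, rep("is_driver", length(genes)),
    rep(driver_label_id(), length(genes))))
  ord <- order(sc, genes, method = "radix")
  out <- data.frame(rank = seq_along(genes), gene = genes[ord],
                    driver_score = sc[ord],
                    assigned_subtype = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(subtypes)) {
    sm <- subtype_score_matrix(model, out$gene, subtypes)
    out$assigned_subtype <- argmin_subtype(sm)
    out <- cbind(out, as.data.frame(sm))
  }
  rownames(out) <- NULL
  class(out) <- c("driver_ranking", "data.frame")
  out
}

#' @export
print.driver_ranking <- function(x, n = 10L, ...) {
  cat("driver ranking:", nrow(x), "genes (lower score = more driver-like)\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}

# genes x subtypes matrix of belongs_to recovery losses
subtype_score_matrix <- function(model, genes, subtypes) {
  sm <- vapply(subtypes, function(s) {
    score_triplets(model, new_triplets(
      genes, rep("belongs_to", length(genes)), rep(s, length(genes))))
  }, numeric(length(genes)))
  sm <- matrix(sm, nrow = length(genes),
               dimnames = list(genes, subtypes))
  sm
}

# arg-min per row with lexicographic tie-break on column name
argmin_subtype <- function(sm) {
  cols <- sort_c(colnames(sm))
  sm <- sm[, cols, drop = FALSE]
  cols[apply(sm, 1L, which.min)]
}

#' Assign a subtype to a gene by minimum belongs-to recovery loss
#'
#' Scores `(gene, belongs_to, S)` for every subtype `S` and returns the
#' arg-min subtype (ties broken lexicographically) together with the
#' full score map, as a subtype-specificity indication for the gene.
#'
#' @param model a fitted [kge_fit()] object.
#' @param gene a gene identifier.
#' @param subtypes subtype labels; default all subtype entities of the
#'   model.
#' @return A list with `subtype` (the arg-min label) and `scores` (named
#'   numeric vector over subtypes).
#' @export
assign_subtype <- function(model, gene, subtypes = NULL) {
  stopifnot(inherits(model, "kge"), length(gene) == 1L)
  if (is.null(subtypes))
    subtypes <- sort_c(model$entities[model$ent_kind == "subtype"])
  stopifnot(length(subtypes) >= 1L)
  sm <- subtype_score_matrix(model, gene, subtypes)
  list(subtype = argmin_subtype(sm), scores = sm[1L, ])
}

#' Write a driver ranking to TSV
#'
#' Deterministic row order (by rank); columns `rank`, `gene`,
#' `driver_score`, `assigned_subtype`, then one column per subtype score.
#'
#' @param ranking a [rank_drivers()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "rank"
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
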