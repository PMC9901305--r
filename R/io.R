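# Readers and writers for the plain-text interchange formats.  All set
# outputs are written in sorted order with fixed number formatting so
# identical inputs give byte-identical files.

#' Read the tabular pipeline inputs
#'
#' `read_mutation_table()`: TSV with header columns `sample_id`,
#' `gene_symbol`, `variant_classification` (17-class MAF dialect).
#' `read_expression_matrix()`: TSV whose first column is `gene_symbol`
#' and remaining columns are one per sample.
#' `read_subtype_table()`: TSV with `sample_id`, `subtype`.
#' `read_edge_table()`: TSV with two gene columns.
#' `read_gene_list()`: one symbol per line, `#` comments and blank lines
#' ignored.
#'
#' @param path input file.
#' @return A data.frame, numeric matrix, or character vector as
#'   appropriate.
#' @name readers
NULL

#' @rdname readers
#' @export
read_mutation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "gene_symbol", "variant_classification")
  if (!all(need %in% names(df)))
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname readers
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_symbol")
    stop("expression matrix must start with a gene_symbol column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("expression matrix has non-numeric entries")
  rownames(m) <- df$gene_symbol
  m
}

#' @rdname readers
#' @export
read_subtype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "subtype") %in% names(df)))
    stop("subtype table must have columns sample_id, subtype")
  df[c("sample_id", "subtype")]
}

#' @rdname readers
#' @export
read_edge_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("edge table needs two gene columns")
  df
}

#' @rdname readers
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Canonical triplet serialization
#'
#' Triplets are written as `head<TAB>relation<TAB>tail`, UTF-8, sorted
#' lexicographically, so equal sets give byte-identical files.
#'
#' @param triplets triplet data.frame (or a knowledge graph).
#' @param path output file.
#' @return `path` (writer) / triplet data.frame (reader), invisibly for
#'   the writer.
#' @export
write_triplets <- function(triplets, path) {
  if (inherits(triplets, "knowledge_graph")) triplets <- triplets$triplets
  tr <- triplets[order(triplets$head, triplets$relation, triplets$tail,
                       method = "radix"), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("head\trelation\ttail",
               paste(tr$head, tr$relation, tr$tail, sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(identical(names(df), c("head", "relation", "tail")))
  new_triplets(df$head, df$relation, df$tail)
}

#' Write / read a synthetic cohort directory
#'
#' Emits `mutations.tsv`, `expression.tsv`, `subtypes.tsv`,
#' `interactions.tsv`, `drivers.txt` and `ground_truth.tsv`
#' (`gene`, `is_driver_truth`, `home_subtype`, `revealed`).  Numeric
#' expression values are written with full (`%.17g`) precision so the
#' round trip is exact and byte-stable.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir` (writer) / a `kg_cohort`-shaped list without ground
#'   truth (reader).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  m <- cohort$mutations
  wt(m[order(m$sample_id, m$gene_symbol, m$variant_classification,
             method = "radix"), ],
     "mutations.tsv")
  ex <- data.frame(gene_symbol = rownames(cohort$expression),
                   apply(cohort$expression, 2L, function(x)
                     sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  wt(ex, "expression.tsv")
  wt(cohort$subtypes[order(cohort$subtypes$sample_id,
                           method = "radix"), ], "subtypes.tsv")
  io <- cohort$interactions
  wt(io[order(io$gene1, io$gene2, method = "radix"), ],
     "interactions.tsv")
  writeLines(c("# known (revealed) benchmark driver genes",
               sort_c(cohort$drivers)), file.path(dir, "drivers.txt"))
  if (!is.null(cohort$truth)) {
    tg <- sort_c(rownames(cohort$expression))
    wt(data.frame(
      gene = tg,
      is_driver_truth = as.integer(tg %in% cohort$truth$driver_set),
      home_subtype = ifelse(tg %in% cohort$truth$driver_set,
                            cohort$truth$home_subtype[tg], "."),
      revealed = as.integer(tg %in% cohort$truth$revealed_benchmark),
      stringsAsFactors = FALSE), "ground_truth.tsv")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subtypes <- read_subtype_table(file.path(dir, "subtypes.tsv"))
  structure(list(
    mutations = read_mutation_table(file.path(dir, "mutations.tsv")),
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    subtypes = subtypes,
    interactions = read_edge_table(file.path(dir, "interactions.tsv")),
    drivers = read_gene_list(file.path(dir, "drivers.txt")),
    vocab = relation_vocabulary(subtypes = sort_c(unique(subtypes$subtype)))
  ), class = "kg_cohort")
}

#' Save / load a fitted embedding model
#'
#' A model directory holds `entities.tsv` (identifier, kind, vector and
#' projection coordinates), `relations.tsv` (identifier, vector,
#' projection, flattened matrix as needed by the variant) and
#' `manifest.txt` (key-value lines: variant, norm, dim, config, content
#' hash).  Values use `%.17g` so the round trip is bit-exact.
#'
#' @param model a fitted [kge_fit()] object.
#' @param dir model directory.
#' @return `dir` (saver) / the restored `"kge"` model (loader).
#' @export
save_kge <- function(model, dir) {
  stopifnot(inherits(model, "kge"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(m) apply(m, 1L, function(x)
    paste(sprintf("%.17g", x), collapse = " "))
  ent <- data.frame(id = model$entities, kind = model$ent_kind,
                    vector = num(model$E), projection = num(model$P),
                    stringsAsFactors = FALSE)
  rel <- data.frame(id = model$relations, vector = num(model$R),
                    projection = num(model$Q), matrix = num(model$M),
                    stringsAsFactors = FALSE)
  write.table(ent, file.path(dir, "entities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rel, file.path(dir, "relations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- model$config
  lines <- c(paste0("variant: ", model$variant),
             paste0("norm: ", model$norm),
             paste0("dim: ", model$dim),
             paste0("subtypes: ",
                    paste(model$vocab$subtypes, collapse = "|")),
             paste0("loss_trace: ",
                    paste(sprintf("%.17g", model$loss_trace),
                          collapse = " ")),
             paste0("initial_loss: ",
                    sprintf("%.17g", model$initial_loss)),
             paste0("final_positive_loss: ",
                    sprintf("%.17g", model$final_positive_loss)),
             vapply(names(cfg), function(k)
               paste0("config.", k, ": ", cfg[[k]]), character(1)))
  lines <- c(lines, paste0("content_md5: ", tools::md5sum(
    c(file.path(dir, "entities.tsv"),
      file.path(dir, "relations.tsv")))[1L]))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname save_kge
#' @export
load_kge <- function(dir) {
  ent <- read.delim(file.path(dir, "entities.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rel <- read.delim(file.path(dir, "relations.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  mf <- readLines(file.path(dir, "manifest.txt"))
  getv <- function(key) {
    ln <- grep(paste0("^", key, ": "), mf, value = TRUE)
    sub(paste0("^", key, ": "), "", ln[1L])
  }
  parse_rows <- function(x) {
    do.call(rbind, lapply(strsplit(x, " ", fixed = TRUE), as.numeric))
  }
  dim <- as.integer(getv("dim"))
  cfg_keys <- sub(":.*$", "", grep("^config\\.", mf, value = TRUE))
  cfg <- lapply(cfg_keys, function(k) {
    v <- getv(k)
    if (grepl("^-?[0-9.e+-]+$", v)) as.numeric(v) else v
  })
  names(cfg) <- sub("^config\\.", "", cfg_keys)
  new_kge(entities = ent$id, relations = rel$id, ent_kind = ent$kind,
          E = parse_rows(ent$vector), P = parse_rows(ent$projection),
          R = parse_rows(rel$vector), Q = parse_rows(rel$projection),
          M = parse_rows(rel$matrix),
          variant = getv("variant"), norm = getv("norm"), dim = dim,
          vocab = relation_vocabulary(
            subtypes = strsplit(getv("subtypes"), "|", fixed = TRUE)[[1L]]),
          loss_trace = as.numeric(strsplit(getv("loss_trace"),
                                           " ")[[1L]]),
          initial_loss = as.numeric(getv("initial_loss")),
          final_positive_loss = as.numeric(getv("final_positive_loss")),
          config = cfg)
}
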