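test_that("aberration triplets: identity, dedup, and distinct-row counts", {
  m1 <- data.frame(sample_id = "S1", gene_symbol = "TP53",
                   variant_classification = "missense mutation")
  expect_equal(build_aberration_triplets(m1),
               kgdriver:::new_triplets("S1", "missense mutation", "TP53"))
  expect_equal(nrow(build_aberration_triplets(rbind(m1, m1))), 1L)

  # 4 samples x 3 genes, 7 distinct rows (one duplicated in the input);
  # expected count from exhaustive enumeration of distinct rows
  rows <- expand.grid(sample_id = paste0("S", 1:4),
                      gene_symbol = paste0("G", 1:3),
                      stringsAsFactors = FALSE)[c(1, 2, 5, 7, 9, 10, 12), ]
  rows$variant_classification <- c("silent", "missense mutation", "IGR",
                                   "intron", "splice site", "silent",
                                   "3' UTR")
  shuffled <- rows[c(3, 1, 2, 7, 4, 5, 6, 1), ]  # with one repeat
  expect_equal(nrow(unique(shuffled)), 7L)
  expect_equal(nrow(build_aberration_triplets(shuffled)), 7L)
})

test_that("aberration triplets reject unknown classes and empty tables warn", {
  m <- data.frame(sample_id = "S1", gene_symbol = "G1",
                  variant_classification = "Missense_Mutation")
  expect_error(build_aberration_triplets(m), "Missense_Mutation")
  empty <- data.frame(sample_id = character(), gene_symbol = character(),
                      variant_classification = character())
  expect_warning(out <- build_aberration_triplets(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("RNA calling: constant rows are silent, outliers are caught", {
  expr <- rbind(FLAT = rep(5, 5), SPIKE = c(1, 1, 1, 1, 100))
  colnames(expr) <- paste0("S", 1:5)
  expect_message(tr <- call_rna_aberrations(expr, 2), "zero MAD")
  # scalar oracle for the spike row: median 1, mad 0 for the four ones ->
  # mad uses all 5 values: median |x - 1| = 0 ... the spike row has
  # mad = 1.4826 * median(|x - med|) = 0; so compute on a spread row too
  expect_equal(nrow(tr[tr$tail == "FLAT", ]), 0L)

  expr2 <- rbind(G1 = c(0, 1, -1, 0.5, -0.5, 100))
  colnames(expr2) <- paste0("S", 1:6)
  med <- median(expr2[1, ]); md <- mad(expr2[1, ])
  z <- (expr2[1, ] - med) / md
  tr2 <- call_rna_aberrations(expr2, 2)
  expect_equal(tr2, kgdriver:::new_triplets(
    names(z)[z >= 2], "over_expression", "G1"))
})

test_that("RNA calling: negating the matrix swaps over and under calls", {
  set.seed(42)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(paste0("G", 1:20), paste0("S", 1:12)))
  expr[3, 1] <- 9; expr[5, 2] <- -9
  a <- call_rna_aberrations(expr, 2)
  b <- call_rna_aberrations(-expr, 2)
  swap <- function(x) ifelse(x == "over_expression", "under_expression",
                             "over_expression")
  a$relation <- swap(a$relation)
  key <- function(tr) sort(kgdriver:::triplet_key(tr))
  expect_equal(key(a), key(b))
})

test_that("interaction/synonym canonicalization dedups and drops loops", {
  expect_equal(build_interaction_triplets(data.frame(a = "A", b = "B")),
               kgdriver:::new_triplets("A", "interaction", "B"))
  expect_equal(nrow(build_interaction_triplets(
    data.frame(a = c("A", "B"), b = c("B", "A")))), 1L)
  expect_equal(nrow(build_interaction_triplets(
    data.frame(a = "A", b = "A"))), 0L)
  syn <- build_synonym_triplets(data.frame(a = c("X", "Y", "X"),
                                           b = c("Y", "X", "X")))
  expect_equal(syn, kgdriver:::new_triplets("X", "synonym", "Y"))
  expect_error(build_interaction_triplets(data.frame(a = c("A", ""),
                                                     b = c("B", "C"))),
               "line")
})

test_that("subtype triplets validate labels and conflicts", {
  v <- relation_vocabulary()
  one <- build_subtype_triplets(data.frame(sample_id = "S1",
                                           subtype = "Luminal A"), v)
  expect_equal(one, kgdriver:::new_triplets("S1", "belongs_to", "Luminal A"))
  expect_error(build_subtype_triplets(
    data.frame(sample_id = c("S1", "S1"),
               subtype = c("Luminal A", "Luminal B")), v), "conflict")
  expect_error(build_subtype_triplets(
    data.frame(sample_id = "S1", subtype = "Basal"), v), "Basal")
  five <- build_subtype_triplets(
    data.frame(sample_id = paste0("S", 1:5), subtype = v$subtypes), v)
  expect_equal(nrow(five), 5L)
})

test_that("driver triplets point at the single driver label and dedup", {
  tr <- build_driver_triplets(c("TP53", "PIK3CA"))
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$tail == driver_label_id()))
  expect_equal(nrow(build_driver_triplets(character())), 0L)
  expect_equal(nrow(build_driver_triplets(c("TP53", "TP53"))), 1L)
})

test_that("assemble_graph takes set unions and derives typed entities", {
  a <- build_driver_triplets(c("G1", "G2", "G3"))
  b <- build_interaction_triplets(data.frame(x = c("G1", "G2", "G4", "G5"),
                                             y = c("G2", "G3", "G5", "G6")))
  g <- assemble_graph(list(a, b))
  expect_equal(nrow(g$triplets), 7L)
  # overlap collapses
  g2 <- assemble_graph(list(a[1:2, ], a[2:3, ]))
  expect_equal(nrow(g2$triplets), 3L)
  expect_setequal(g$entities$kind[g$entities$id == "D"], "driver_label")
  # schema closure: every relation used is in the vocabulary
  kt <- kgdriver:::relation_kind_table(g$vocab)
  expect_true(all(g$triplets$relation %in% kt$relation))
})

test_that("assemble_graph rejects kind collisions by name", {
  mut <- build_aberration_triplets(data.frame(
    sample_id = "X1", gene_symbol = "G1",
    variant_classification = "silent"))
  drv <- build_driver_triplets("X1")  # X1 now also claimed as a gene
  expect_error(assemble_graph(list(mut, drv)), "X1")
})

test_that("triplet membership lookup agrees with the triplet set", {
  g <- toy_graph()
  expect_true(has_triplet(g, "G1", "is_driver", "D"))
  expect_false(has_triplet(g, "G3", "is_driver", "D"))
  keys <- kgdriver:::triplet_key(g$triplets)
  expect_true(all(mapply(has_triplet, list(g), g$triplets$head,
                         g$triplets$relation, g$triplets$tail)))
})
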