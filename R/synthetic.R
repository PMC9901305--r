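#' Parameters of the synthetic tumour-cohort generator
#'
#' Defines a cohort with planted, subtype-specific driver genes.  Samples
#' receive subtypes uniformly; each planted driver gets a home subtype
#' round-robin.  A driver is DNA-aberrant in its home-subtype samples at
#' rate `driver_mut_rate`; its rate outside the home subtype is derived
#' so that, in expectation, a fraction `subtype_exclusivity` of its
#' aberrant samples carry the home subtype (see
#' [driver_mutation_rates()]).  Passenger genes are aberrant uniformly at
#' `passenger_mut_rate`.  Variant classes are drawn uniformly from the
#' 17-class DNA vocabulary.  A mutated driver cell also acquires an RNA
#' aberration with probability `rna_coupling` (expression shift of +4 or
#' -4 on a N(0,1) baseline, direction equiprobable).  Gene-gene
#' interaction edges are Bernoulli per pair, denser among drivers than in
#' the background.  A fraction `benchmark_fraction` of the planted
#' drivers is revealed as the known-driver list; the rest stay hidden
#' and can only be recovered from the data.
#'
#' @param n_samples,n_genes,n_drivers,n_subtypes cohort dimensions.
#' @param driver_mut_rate per-sample DNA aberration probability of a
#'   driver within its home subtype.
#' @param passenger_mut_rate per-sample aberration probability of
#'   non-driver genes (and baseline noise).
#' @param rna_coupling probability that a mutated driver cell also shows
#'   an expression aberration.
#' @param subtype_exclusivity expected fraction of a driver's aberrant
#'   samples confined to its home subtype (1 = fully exclusive).
#' @param interaction_density_driver,interaction_density_background edge
#'   probability for driver-driver vs all other gene pairs.
#' @param benchmark_fraction fraction of planted drivers revealed as
#'   "known".
#' @param z_threshold robust z cutoff used when calling RNA aberrations
#'   from the emitted expression matrix.
#' @param seed integer seed; the whole cohort is a deterministic
#'   function of it.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_samples = 200L, n_genes = 300L, n_drivers = 20L,
                       n_subtypes = 5L, driver_mut_rate = 0.35,
                       passenger_mut_rate = 0.03, rna_coupling = 0.5,
                       subtype_exclusivity = 0.8,
                       interaction_density_driver = 0.3,
                       interaction_density_background = 0.01,
                       benchmark_fraction = 0.6, z_threshold = 2,
                       seed = 1L) {
  p <- list(n_samples = as.integer(n_samples),
            n_genes = as.integer(n_genes),
            n_drivers = as.integer(n_drivers),
            n_subtypes = as.integer(n_subtypes),
            driver_mut_rate = driver_mut_rate,
            passenger_mut_rate = passenger_mut_rate,
            rna_coupling = rna_coupling,
            subtype_exclusivity = subtype_exclusivity,
            interaction_density_driver = interaction_density_driver,
            interaction_density_background = interaction_density_background,
            benchmark_fraction = benchmark_fraction,
            z_threshold = z_threshold,
            seed = as.integer(seed))
  probs <- c("driver_mut_rate", "passenger_mut_rate", "rna_coupling",
             "subtype_exclusivity", "interaction_density_driver",
             "interaction_density_background", "benchmark_fraction")
  for (nm in probs)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must be a probability in [0, 1]")
  if (p$n_drivers >= p$n_genes) stop("n_drivers must be < n_genes")
  if (p$n_subtypes < 2L) stop("n_subtypes must be >= 2")
  if (p$n_samples < p$n_subtypes)
    stop("need at least one sample per subtype")
  class(p) <- "sim_params"
  p
}

subtype_labels <- function(n_subtypes) {
  base <- c("Luminal A", "Luminal B", "HER2-enriched", "Triple-negative",
            "Normal-like")
  if (n_subtypes <= length(base)) base[seq_len(n_subtypes)]
  else paste0("Subtype_", seq_len(n_subtypes))
}

#' Home and away mutation rates of a planted driver
#'
#' Given `n_home` home-subtype samples out of `n`, the home rate is
#' `driver_mut_rate` and the away rate solves
#' `n_home * p_home * (1 - excl) = excl * n_away * p_away`
#' so that the expected fraction of aberrant samples in the home subtype
#' equals `subtype_exclusivity` (capped at 1; zero when exclusivity is
#' 1).
#'
#' @param p a [sim_params()] object.
#' @param n_home number of samples in the driver's home subtype.
#' @return List with `p_home`, `p_away`, and `expected`/`sd` of the
#'   driver's aberrant-sample count.
#' @export
driver_mutation_rates <- function(p, n_home) {
  n_away <- p$n_samples - n_home
  p_home <- p$driver_mut_rate
  excl <- p$subtype_exclusivity
  p_away <- if (excl >= 1 || n_away == 0L) 0
            else min(1, p_home * n_home * (1 - excl) / (excl * n_away))
  list(p_home = p_home, p_away = p_away,
       expected = n_home * p_home + n_away * p_away,
       sd = sqrt(n_home * p_home * (1 - p_home) +
                 n_away * p_away * (1 - p_away)))
}

#' Generate a synthetic cohort with planted subtype-specific drivers
#'
#' Produces the five input tables of the pipeline (mutations, expression,
#' subtype annotations, interactions, known-driver list) plus a
#' ground-truth record: the planted driver set, each driver's home
#' subtype, the revealed benchmark subset, and the full triplet ledger
#' the knowledge graph built from the emitted tables must reproduce.
#'
#' @param p a [sim_params()] object.
#' @return A list of class `"kg_cohort"` with elements `mutations`,
#'   `expression`, `subtypes`, `interactions`, `drivers` (the revealed
#'   list), `truth` (see above) and `vocab`.
#' @export
simulate_cohort <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  wid_s <- max(3L, nchar(p$n_samples))
  wid_g <- max(3L, nchar(p$n_genes))
  samples <- sprintf("S%0*d", wid_s, seq_len(p$n_samples))
  genes <- sprintf("G%0*d", wid_g, seq_len(p$n_genes))
  labels <- subtype_labels(p$n_subtypes)
  vocab <- relation_vocabulary(subtypes = labels)

  sub_of <- stats::setNames(sample(labels, p$n_samples, replace = TRUE),
                            samples)
  drivers <- sort_c(sample(genes, p$n_drivers))
  home <- stats::setNames(
    labels[(seq_len(p$n_drivers) - 1L) %% p$n_subtypes + 1L], drivers)

  # DNA aberrations
  mut_s <- character(0); mut_g <- character(0)
  for (g in genes) {
    if (g %in% drivers) {
      is_home <- sub_of == home[[g]]
      rates <- driver_mutation_rates(p, sum(is_home))
      pr <- ifelse(is_home, rates$p_home, rates$p_away)
    } else {
      pr <- rep(p$passenger_mut_rate, p$n_samples)
    }
    hit <- runif(p$n_samples) < pr
    mut_s <- c(mut_s, samples[hit])
    mut_g <- c(mut_g, rep(g, sum(hit)))
  }
  mutations <- data.frame(
    sample_id = mut_s, gene_symbol = mut_g,
    variant_classification = if (length(mut_s))
      sample(vocab$dna_types, length(mut_s), replace = TRUE)
      else character(0),
    stringsAsFactors = FALSE)

  # RNA expression: N(0,1) baseline, +-4 shift on coupled driver cells
  expr <- matrix(rnorm(p$n_genes * p$n_samples), p$n_genes, p$n_samples,
                 dimnames = list(genes, samples))
  drv_mut <- mutations$gene_symbol %in% drivers
  if (any(drv_mut)) {
    cells <- unique(mutations[drv_mut, c("sample_id", "gene_symbol")])
    coupled <- runif(nrow(cells)) < p$rna_coupling
    if (any(coupled)) {
      shift <- ifelse(runif(sum(coupled)) < 0.5, 4, -4)
      idx <- cbind(match(cells$gene_symbol[coupled], genes),
                   match(cells$sample_id[coupled], samples))
      expr[idx] <- expr[idx] + shift
    }
  }

  subtypes <- data.frame(sample_id = samples,
                         subtype = unname(sub_of),
                         stringsAsFactors = FALSE)

  # interactions: denser among drivers
  pairs <- t(utils::combn(genes, 2L))
  dd <- pairs[, 1L] %in% drivers & pairs[, 2L] %in% drivers
  dens <- ifelse(dd, p$interaction_density_driver,
                 p$interaction_density_background)
  keep <- runif(nrow(pairs)) < dens
  interactions <- data.frame(gene1 = pairs[keep, 1L],
                             gene2 = pairs[keep, 2L],
                             stringsAsFactors = FALSE)

  n_rev <- max(1L, round(p$benchmark_fraction * p$n_drivers))
  revealed <- sort_c(sample(drivers, n_rev))

  cohort <- list(mutations = mutations, expression = expr,
                 subtypes = subtypes, interactions = interactions,
                 drivers = revealed, vocab = vocab)
  cohort$truth <- list(
    driver_set = drivers, home_subtype = home,
    revealed_benchmark = revealed, params = p,
    ledger = cohort_triplets(cohort, p$z_threshold))
  class(cohort) <- "kg_cohort"
  cohort
}

#' @export
print.kg_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d samples, %d genes (%d planted drivers, %d revealed), %d mutation rows, %d interactions\n",
    ncol(x$expression), nrow(x$expression),
    length(x$truth$driver_set), length(x$drivers),
    nrow(x$mutations), nrow(x$interactions)))
  invisible(x)
}

# all triplet sets of a cohort, as one deduplicated set
cohort_triplets <- function(cohort, z_threshold = 2) {
  unique(rbind(
    build_aberration_triplets(cohort$mutations, cohort$vocab),
    call_rna_aberrations(cohort$expression, z_threshold),
    build_interaction_triplets(cohort$interactions),
    build_subtype_triplets(cohort$subtypes, cohort$vocab),
    build_driver_triplets(cohort$drivers)))
}

#' Build the knowledge graph of a cohort
#'
#' Convenience wrapper running all five triplet builders and
#' [assemble_graph()].
#'
#' @param cohort a [simulate_cohort()] result (or a list with the same
#'   elements read from disk, see [read_cohort()]).
#' @param z_threshold robust z cutoff for RNA aberration calling.
#' @return A knowledge graph.
#' @export
build_cohort_graph <- function(cohort, z_threshold = 2) {
  assemble_graph(cohort_triplets(cohort, z_threshold), cohort$vocab)
}

#' Check that emitted cohort files reproduce the ground-truth ledger
#'
#' Reads a cohort back from `dir`, rebuilds the full triplet set with the
#' graph builders, and compares it with the generator's ledger.
#'
#' @param dir directory written by [write_cohort()].
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @return `TRUE` on exact agreement, otherwise `FALSE` with attribute
#'   `"diff"` holding the symmetric difference, plus a warning.
#' @export
verify_ledger <- function(dir, truth) {
  cohort <- read_cohort(dir)
  rebuilt <- cohort_triplets(cohort, truth$params$z_threshold)
  a <- sort_c(triplet_key(rebuilt))
  b <- sort_c(triplet_key(truth$ledger))
  if (identical(a, b)) return(TRUE)
  diff <- c(setdiff(a, b), setdiff(b, a))
  warning("ledger mismatch: ", length(diff),
          " triplet(s) in the symmetric difference")
  structure(FALSE, diff = gsub("\r", "\t", diff, fixed = TRUE))
}
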