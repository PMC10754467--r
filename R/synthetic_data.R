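# Synthetic scRNA-seq-like matrices with planted subtypes and drivers, so
# every pipeline stage is testable without external data.

#' Synthetic-data scenario
#'
#' Describes a non-negative log-expression matrix with dropout zeros,
#' planted subtype structure and planted subtype-specific up-regulated
#' driver genes. The defaults are the package's standard recovery scenario:
#' 200 cells, 100 genes, 2 balanced subtypes with 10 disjoint drivers each,
#' an effect shift of 2 log-units, 30% dropout and within-gene noise sd 0.5.
#'
#' @param m_cells,n_genes Matrix dimensions.
#' @param n_subtypes Number of planted subtypes.
#' @param drivers_per_subtype Planted up-regulated genes per subtype
#'   (disjoint across subtypes; `n_subtypes * drivers_per_subtype` must not
#'   exceed `n_genes`).
#' @param effect_shift Additive up-shift of a subtype's drivers in that
#'   subtype's cells, in log-expression units.
#' @param dropout_rate Probability that any entry is zeroed (dropout),
#'   in \[0, 1).
#' @param baseline_shape Shape of the gamma-distributed per-gene baseline
#'   log-expression (rate 1, so the mean baseline equals the shape).
#' @param noise_sd Standard deviation of the per-entry Gaussian noise.
#' @param program_sd Cell-to-cell standard deviation of the driver-program
#'   activity (default 0.25). Each cell carries an activity factor
#'   `a ~ N(1, program_sd)` multiplying the effect shift on its own
#'   subtype's driver genes, so a subtype's drivers co-vary across its
#'   cells — the intra-association that makes them a module rather than a
#'   set of independently shifted genes. The mean shift stays
#'   `effect_shift`. Set to 0 for a deterministic shift.
#' @param subtype_proportions Simplex vector of subtype sizes (default
#'   equal).
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(m_cells = 200, n_genes = 100, n_subtypes = 2,
                               drivers_per_subtype = 10, effect_shift = 2,
                               dropout_rate = 0.3, baseline_shape = 1,
                               noise_sd = 0.5, program_sd = 0.25,
                               subtype_proportions = NULL,
                               seed = 1) {
  if (m_cells < 1 || n_genes < 1) stop_scdrivers("m_cells and n_genes must be >= 1")
  if (n_subtypes < 1) stop_scdrivers("n_subtypes must be >= 1")
  if (drivers_per_subtype < 1) stop_scdrivers("drivers_per_subtype must be >= 1")
  if (n_subtypes * drivers_per_subtype > n_genes) {
    stop_scdrivers("n_subtypes * drivers_per_subtype exceeds n_genes")
  }
  if (effect_shift < 0) stop_scdrivers("effect_shift must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_scdrivers("dropout_rate must lie in [0, 1)")
  }
  if (baseline_shape <= 0) stop_scdrivers("baseline_shape must be positive")
  if (noise_sd < 0) stop_scdrivers("noise_sd must be >= 0")
  if (program_sd < 0) stop_scdrivers("program_sd must be >= 0")
  if (is.null(subtype_proportions)) {
    subtype_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  if (length(subtype_proportions) != n_subtypes ||
      abs(sum(subtype_proportions) - 1) > 1e-8 ||
      any(subtype_proportions <= 0)) {
    stop_scdrivers("subtype_proportions must be a positive vector of length ",
                   n_subtypes, " summing to 1")
  }
  structure(list(m_cells = as.integer(m_cells), n_genes = as.integer(n_genes),
                 n_subtypes = as.integer(n_subtypes),
                 drivers_per_subtype = as.integer(drivers_per_subtype),
                 effect_shift = effect_shift, dropout_rate = dropout_rate,
                 baseline_shape = baseline_shape, noise_sd = noise_sd,
                 program_sd = program_sd,
                 subtype_proportions = subtype_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Deterministic subtype label counts from proportions (largest remainder),
# then a seeded shuffle.
proportion_counts <- function(m, props) {
  raw <- props * m
  counts <- floor(raw)
  rem <- m - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a planted-subtype expression matrix
#'
#' Per gene, a gamma-shaped positive baseline; per entry, additive Gaussian
#' noise; cells of subtype k get `effect_shift` times their own program
#' activity (`~ N(1, program_sd)`) added on that subtype's driver genes, so
#' the planted drivers form a co-varying module within each subtype; values
#' are clipped at 0 and finally zeroed independently with probability
#' `dropout_rate`. The dropout mask is drawn last, so two scenarios
#' differing only in `dropout_rate` share the same pre-dropout matrix under
#' the same seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (`labels` per cell, `driver_sets` per subtype).
#' @export
simulate_subtypes <- function(scenario) {
  sc <- scenario
  local_seed(sc$seed, {
    counts <- proportion_counts(sc$m_cells, sc$subtype_proportions)
    labels <- sample(rep(seq_len(sc$n_subtypes), counts))
    driver_idx <- sample(sc$n_genes, sc$n_subtypes * sc$drivers_per_subtype)
    driver_sets <- split(driver_idx,
                         rep(seq_len(sc$n_subtypes),
                             each = sc$drivers_per_subtype))
    baseline <- stats::rgamma(sc$n_genes, shape = sc$baseline_shape, rate = 1)
    vals <- matrix(rep(baseline, each = sc$m_cells), sc$m_cells, sc$n_genes) +
      matrix(stats::rnorm(sc$m_cells * sc$n_genes, sd = sc$noise_sd),
             sc$m_cells, sc$n_genes)
    activity <- 1 + stats::rnorm(sc$m_cells, sd = sc$program_sd)
    for (k in seq_len(sc$n_subtypes)) {
      cells_k <- which(labels == k)
      vals[cells_k, driver_sets[[k]]] <-
        vals[cells_k, driver_sets[[k]]] + sc$effect_shift * activity[cells_k]
    }
    vals[vals < 0] <- 0
    if (sc$dropout_rate > 0) {
      drop_mask <- matrix(stats::runif(sc$m_cells * sc$n_genes) <
                            sc$dropout_rate, sc$m_cells, sc$n_genes)
      vals[drop_mask] <- 0
    }
    gene_names <- sprintf("gene%03d", seq_len(sc$n_genes))
    x <- expression_matrix(vals, gene_names = gene_names,
                           cell_ids = sprintf("cell%04d", seq_len(sc$m_cells)))
    truth <- list(labels = labels,
                  driver_sets = lapply(driver_sets,
                                       function(i) gene_names[i]),
                  program_activity = activity)
    list(matrix = x, truth = truth, scenario = sc)
  })
}

#' Generate a two-group (tumor vs non-tumor) matrix
#'
#' Emulates the differential-expression stage's input: the first half of the
#' cells are flagged `tumor`, and `n_deg` randomly chosen genes are shifted
#' up by `deg_shift` in the tumor cells. No subtype structure is planted;
#' baseline, noise, clipping and dropout behave as in
#' [simulate_subtypes()].
#'
#' @param scenario A [synthetic_scenario()] (its subtype fields are ignored).
#' @param n_deg Number of planted differentially expressed genes
#'   (0 <= n_deg <= n_genes).
#' @param deg_shift Additive shift of the planted genes in tumor cells.
#' @return A list with `matrix`, `annotation` (a [cell_annotation()] of
#'   tumor/nontumor) and `truth` (`deg_genes`).
#' @export
simulate_two_group <- function(scenario, n_deg, deg_shift) {
  sc <- scenario
  if (n_deg < 0 || n_deg > sc$n_genes) {
    stop_scdrivers("n_deg must lie in [0, n_genes]")
  }
  local_seed(sc$seed, {
    group <- rep(c("tumor", "nontumor"),
                 c(ceiling(sc$m_cells / 2), floor(sc$m_cells / 2)))
    deg_idx <- if (n_deg > 0) sample(sc$n_genes, n_deg) else integer(0)
    baseline <- stats::rgamma(sc$n_genes, shape = sc$baseline_shape, rate = 1)
    vals <- matrix(rep(baseline, each = sc$m_cells), sc$m_cells, sc$n_genes) +
      matrix(stats::rnorm(sc$m_cells * sc$n_genes, sd = sc$noise_sd),
             sc$m_cells, sc$n_genes)
    if (n_deg > 0) {
      vals[group == "tumor", deg_idx] <-
        vals[group == "tumor", deg_idx] + deg_shift
    }
    vals[vals < 0] <- 0
    if (sc$dropout_rate > 0) {
      drop_mask <- matrix(stats::runif(sc$m_cells * sc$n_genes) <
                            sc$dropout_rate, sc$m_cells, sc$n_genes)
      vals[drop_mask] <- 0
    }
    gene_names <- sprintf("gene%03d", seq_len(sc$n_genes))
    cell_ids <- sprintf("cell%04d", seq_len(sc$m_cells))
    x <- expression_matrix(vals, gene_names = gene_names, cell_ids = cell_ids)
    list(matrix = x,
         annotation = cell_annotation(cell_ids, group),
         truth = list(deg_genes = gene_names[sort(deg_idx)]),
         scenario = sc)
  })
}
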