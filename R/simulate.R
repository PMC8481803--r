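# Seeded synthetic-data generators with known ground truth for every
# pipeline: bulk two-group matrices, gene set collections with one planted
# category, random DAGs with an injected deregulated path, three-group
# single-cell counts with a planted program, regulator-target tables with
# one causal activator, and time courses with planted shapes.

#' Simulate a two-group bulk expression matrix
#'
#' Baseline log2 intensities are drawn per gene from a uniform band and
#' perturbed with Gaussian noise per sample (a log-normal intensity
#' model). A planted subset of genes is shifted upward by `effect` log2
#' units in group A. Values are returned on the log2 scale in
#' `normalized` mode.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_genes Number of genes (default 1000).
#' @param n_per_group Samples per group (default 10).
#' @param n_de Number of planted differentially expressed genes
#'   (default 50).
#' @param effect Log2 shift of planted genes in group A (default 2).
#' @param noise_sd Per-sample Gaussian noise on the log2 scale (default 1).
#' @return A list: `matrix` (`tk_expr`), `groups` (tibble `id`, `group`
#'   with labels A/B), `truth` (list with `de_genes`, `effect`).
#' @export
make_bulk <- function(seed, n_genes = 1000, n_per_group = 10, n_de = 50,
                      effect = 2, noise_sd = 1) {
  stopifnot(n_per_group >= 3, n_de <= n_genes)
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    ids <- c(
      sprintf("A%02d", seq_len(n_per_group)),
      sprintf("B%02d", seq_len(n_per_group))
    )
    group <- rep(c("A", "B"), each = n_per_group)
    mu <- stats::runif(n_genes, 4, 10)
    x <- matrix(
      stats::rnorm(n_genes * 2 * n_per_group, mean = mu, sd = noise_sd),
      nrow = n_genes, dimnames = list(genes, ids)
    )
    de_genes <- sort(sample(genes, n_de))
    x[de_genes, group == "A"] <- x[de_genes, group == "A"] + effect
    list(
      matrix = expr_mat(x,
        col_data = tibble::tibble(id = ids, group = group),
        mode = "normalized"
      ),
      groups = tibble::tibble(id = ids, group = group),
      truth = list(de_genes = de_genes, effect = effect)
    )
  })
}

#' Simulate a gene set collection with one planted category
#'
#' Builds `n_decoys` decoy sets with members drawn uniformly from the
#' universe, plus one planted set consisting of the given planted genes
#' padded with a small random remainder (so the planted set's overlap with
#' the truth is at least 80% by construction).
#'
#' @param seed Integer seed.
#' @param universe Character vector of all gene tokens.
#' @param planted_genes Genes forming the planted category's core.
#' @param n_decoys Number of decoy sets (default 50).
#' @param size_range Inclusive decoy size bounds (default 10-60).
#' @param padding_frac Fraction of extra random members added to the
#'   planted set (default 0.1).
#' @param planted_name Name of the planted set.
#' @return A list: `sets` (`tk_gene_sets`), `truth` (list with
#'   `planted_set`, `planted_genes`).
#' @export
make_genesets <- function(seed, universe, planted_genes, n_decoys = 50,
                          size_range = c(10, 60), padding_frac = 0.1,
                          planted_name = "planted_program") {
  universe <- unique(normalize_genes(universe, "universe gene"))
  planted_genes <- unique(normalize_genes(planted_genes, "planted gene"))
  stopifnot(all(planted_genes %in% universe))
  withr::with_seed(seed, {
    pad_n <- ceiling(padding_frac * length(planted_genes))
    pad <- sample(setdiff(universe, planted_genes), pad_n)
    sizes <- sample(size_range[1]:size_range[2], n_decoys, replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    decoys <- lapply(sizes, function(s) sample(universe, s))
    sets <- gene_sets(
      set = c(planted_name, sprintf("decoy_%03d", seq_len(n_decoys))),
      genes = c(list(c(planted_genes, pad)), decoys)
    )
    list(
      sets = sets,
      truth = list(planted_set = planted_name, planted_genes = planted_genes)
    )
  })
}

#' Simulate a directed acyclic gene network with an injected path
#'
#' Draws an Erdos-Renyi DAG over a topological order of the chosen nodes
#' and injects a simple directed path through the top-ranked genes of the
#' supplied score list, so the most deregulated path is known by
#' construction.
#'
#' @param seed Integer seed.
#' @param ranked A tibble `gene`, `score` (the ranking the path search
#'   will use).
#' @param n_nodes Total nodes in the network (default 30).
#' @param path_length Nodes in the injected path (default 5); the injected
#'   path runs through the `path_length` top-ranked genes in rank order.
#' @param p_edge Edge probability between topologically ordered node pairs
#'   (default 0.15).
#' @return A list: `network` (`tk_network`), `truth` (list with
#'   `path_nodes` in order).
#' @export
make_network <- function(seed, ranked, n_nodes = 30, path_length = 5,
                         p_edge = 0.15) {
  ranked <- as_ranked_list(ranked)
  stopifnot(path_length >= 2, n_nodes >= path_length,
    n_nodes <= nrow(ranked))
  withr::with_seed(seed, {
    path_nodes <- ranked$gene[seq_len(path_length)]
    others <- sample(
      setdiff(ranked$gene, path_nodes), n_nodes - path_length
    )
    # topological order: injected path first, in sequence
    topo <- c(path_nodes, others)
    from <- character(0)
    to <- character(0)
    for (i in seq_len(n_nodes - 1)) {
      pick <- stats::runif(n_nodes - i) < p_edge
      from <- c(from, rep(topo[i], sum(pick)))
      to <- c(to, topo[seq(i + 1, n_nodes)][pick])
    }
    from <- c(from, path_nodes[-path_length])
    to <- c(to, path_nodes[-1])
    list(
      network = gene_network(from, to),
      truth = list(path_nodes = path_nodes)
    )
  })
}

#' Simulate three-group single-cell counts with a planted program
#'
#' Emulates the structure of a three-group clinical single-cell
#' comparison (severe / moderate / healthy): negative-binomial counts with
#' gene-specific log-normal baseline means, a planted gene program whose
#' members are up-shifted (multiplied by `program_fold`) in one group's
#' cells, per-group sample labels for pseudo-bulk aggregation, and a
#' configurable number of deliberately low-coverage cells that fail
#' quality control.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 1200).
#' @param cells_per_group Named integer vector of cells per group
#'   (default 120 each of ARDS, NonVent, Healthy).
#' @param n_program Planted program size (default 40).
#' @param program_group Group whose cells express the program
#'   (default `"ARDS"`).
#' @param program_fold Multiplier on program gene means in the program
#'   group (default 4).
#' @param samples_per_group Sample labels per group for pseudo-bulk
#'   (default 2).
#' @param n_fail_per_group Deliberately failing-QC cells added per group
#'   (default 3); their mean coverage is 2% of a normal cell.
#' @param mean_sdlog Spread of the log-normal baseline gene means
#'   (default 1).
#' @param base_mu Average counts per gene per cell before scaling
#'   (default 2).
#' @param dispersion Negative-binomial size parameter (default 2).
#' @return A list: `matrix` (`tk_expr` counts, cells in columns),
#'   `cell_data` (tibble `id`, `group`, `sample`), `truth` (list with
#'   `program_genes`, `program_group`, `failing_cells`).
#' @export
make_single_cell <- function(seed, n_genes = 1200,
                             cells_per_group = c(
                               ARDS = 120, NonVent = 120, Healthy = 120
                             ),
                             n_program = 40, program_group = "ARDS",
                             program_fold = 4, samples_per_group = 2,
                             n_fail_per_group = 3, mean_sdlog = 1,
                             base_mu = 2, dispersion = 2) {
  stopifnot(program_group %in% names(cells_per_group))
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    program_genes <- sort(sample(genes, n_program))
    groups <- names(cells_per_group)
    n_ok <- sum(cells_per_group)
    cell_group <- c(
      rep(groups, times = cells_per_group),
      rep(groups, each = n_fail_per_group)
    )
    failing <- c(
      rep(FALSE, n_ok), rep(TRUE, n_fail_per_group * length(groups))
    )
    cells <- sprintf("CELL%05d", seq_along(cell_group))
    base_mean <- stats::rlnorm(n_genes, meanlog = log(base_mu) -
      mean_sdlog^2 / 2, sdlog = mean_sdlog)
    mu <- matrix(base_mean, nrow = n_genes, ncol = length(cells))
    is_prog_gene <- genes %in% program_genes
    mu[is_prog_gene, cell_group == program_group] <-
      mu[is_prog_gene, cell_group == program_group] * program_fold
    mu[, failing] <- mu[, failing] * 0.02
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = dispersion),
      nrow = n_genes, dimnames = list(genes, cells)
    )
    # sample labels cycle within each group's cells
    sample_label <- character(length(cell_group))
    for (g in groups) {
      idx <- which(cell_group == g)
      sample_label[idx] <- paste0(
        g, "_s", 1 + (seq_along(idx) - 1) %% samples_per_group
      )
    }
    cell_data <- tibble::tibble(
      id = cells, group = cell_group, sample = sample_label
    )
    list(
      matrix = expr_mat(counts, col_data = cell_data, mode = "counts"),
      cell_data = cell_data,
      truth = list(
        program_genes = program_genes,
        program_group = program_group,
        failing_cells = cells[failing]
      )
    )
  })
}

#' Simulate a regulator-target interaction table with one causal regulator
#'
#' Appends regulator expression rows to a bulk fixture matrix and returns
#' an interaction table in which one causal regulator targets the planted
#' differentially expressed genes while decoy regulators target random
#' genes. The causal regulator's expression row is generated to correlate
#' (Pearson, generating correlation `rho`) with the standardized mean
#' profile of its targets; decoy rows are independent noise.
#'
#' @param seed Integer seed.
#' @param bulk Output of [make_bulk()].
#' @param n_regulators Total regulators (default 20; one causal).
#' @param targets_per_decoy Targets drawn uniformly per decoy
#'   (default 40).
#' @param rho Generating correlation of the causal regulator with its
#'   target mean profile (default 0.8).
#' @return A list: `rti` (`tk_rti`), `matrix` (`tk_expr` with regulator
#'   rows appended), `truth` (list with `causal_regulator`,
#'   `causal_targets`).
#' @export
make_rti <- function(seed, bulk, n_regulators = 20, targets_per_decoy = 40,
                     rho = 0.8) {
  stopifnot(n_regulators >= 2, rho > -1, rho < 1)
  m <- bulk$matrix
  x <- expr_values(m)
  withr::with_seed(seed, {
    regs <- sprintf("TF%02d", seq_len(n_regulators))
    causal <- sample(regs, 1)
    causal_targets <- bulk$truth$de_genes
    target_profile <- colMeans(t(scale(t(x[causal_targets, , drop = FALSE]))))
    target_profile <- as.numeric(scale(target_profile))
    reg_rows <- matrix(
      stats::rnorm(n_regulators * ncol(x), mean = 6, sd = 1),
      nrow = n_regulators, dimnames = list(regs, colnames(x))
    )
    reg_rows[causal, ] <- 6 + rho * target_profile +
      sqrt(1 - rho^2) * stats::rnorm(ncol(x))
    pairs <- purrr::map(regs, function(r) {
      if (r == causal) {
        tibble::tibble(regulator = r, target = causal_targets)
      } else {
        tibble::tibble(
          regulator = r,
          target = sample(rownames(x), targets_per_decoy)
        )
      }
    })
    pairs <- dplyr::bind_rows(pairs)
    aug <- rbind(x, reg_rows)
    list(
      rti = rti_table(pairs$regulator, pairs$target),
      matrix = expr_mat(aug, col_data = m$col_data, mode = m$mode),
      truth = list(
        causal_regulator = causal, causal_targets = causal_targets
      )
    )
  })
}

#' Simulate time courses with planted shape families
#'
#' Generates monotone-up, monotone-down, and transient-peak shapes of
#' amplitude `amplitude` plus flat noise genes, all with Gaussian noise.
#'
#' @param seed Integer seed.
#' @param timepoints Strictly increasing sampling times
#'   (default 0, 2, 4, 8, 12, 24).
#' @param n_per_shape Genes per planted shape family (default 10).
#' @param n_flat Flat noise genes (default 30).
#' @param amplitude Shape amplitude (default 4).
#' @param noise_sd Gaussian noise standard deviation (default 0.3).
#' @return A list: `courses` (`tk_timecourse`), `truth` (tibble `gene`,
#'   `shape` in up/down/peak/flat).
#' @export
make_timecourses <- function(seed, timepoints = c(0, 2, 4, 8, 12, 24),
                             n_per_shape = 10, n_flat = 30, amplitude = 4,
                             noise_sd = 0.3) {
  withr::with_seed(seed, {
    tp <- as.numeric(timepoints)
    u <- (tp - min(tp)) / (max(tp) - min(tp))
    shapes <- list(
      up = amplitude * u,
      down = amplitude * (1 - u),
      peak = amplitude * (1 - abs(2 * u - 1))
    )
    n_total <- 3 * n_per_shape + n_flat
    genes <- sprintf("T%03d", seq_len(n_total))
    shape_label <- c(
      rep(names(shapes), each = n_per_shape), rep("flat", n_flat)
    )
    base <- t(vapply(shape_label, function(s) {
      if (s == "flat") rep(0, length(tp)) else shapes[[s]]
    }, numeric(length(tp))))
    values <- base + matrix(
      stats::rnorm(n_total * length(tp), sd = noise_sd),
      nrow = n_total
    )
    rownames(values) <- genes
    list(
      courses = time_course(values, tp),
      truth = tibble::tibble(gene = genes, shape = shape_label)
    )
  })
}
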