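# Prioritization of transcriptional regulators from regulator-target
# interactions (RTIs), a sorted gene list, and an expression matrix.

#' Construct a regulator-target interaction table
#'
#' @param regulator,target Character vectors of equal length. Duplicate
#'   pairs are collapsed; self-regulation (regulator == target) is allowed
#'   but counted in the `self_interactions` attribute.
#' @return A tibble of class `tk_rti` with columns `regulator`, `target`.
#' @export
rti_table <- function(regulator, target) {
  stopifnot(length(regulator) == length(target))
  out <- tibble::tibble(
    regulator = normalize_genes(regulator, "regulator"),
    target = normalize_genes(target, "target")
  )
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, .data$regulator, .data$target)
  attr(out, "self_interactions") <- sum(out$regulator == out$target)
  class(out) <- c("tk_rti", class(out))
  out
}

#' Read a two-column regulator-target TSV
#'
#' @param path File with lines `regulator<TAB>target`.
#' @return A `tk_rti` tibble (see [rti_table()]).
#' @export
read_rti_tsv <- function(path) {
  if (!file.exists(path)) stop("RTI file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad)) {
    stop("Malformed RTI line ", bad[1], ": expected 2 fields.", call. = FALSE)
  }
  rti_table(
    vapply(fields, `[[`, character(1), 1),
    vapply(fields, `[[`, character(1), 2)
  )
}

#' Mean regulator-target expression correlation
#'
#' Mean of the Pearson correlations between the regulator's expression row
#' and each target's row, over targets present in the matrix with
#' non-constant rows (constant-row targets are skipped and counted in the
#' `n_skipped` attribute). A constant regulator row yields `NA`
#' (undetermined), not an error.
#'
#' @param m A `tk_expr` matrix with at least 3 columns.
#' @param regulator Gene token of the regulator (must be a matrix row).
#' @param targets Character vector of target genes.
#' @return Numeric scalar in \[-1, 1\] (or `NA`), with attributes `n_used`
#'   and `n_skipped`.
#' @export
mean_target_correlation <- function(m, regulator, targets) {
  x <- expr_values(m)
  if (ncol(x) < 3) stop("Need at least 3 samples.", call. = FALSE)
  regulator <- normalize_genes(regulator, "regulator")
  targets <- unique(normalize_genes(targets, "target"))
  if (!regulator %in% rownames(x)) {
    stop("Regulator not in matrix: ", regulator, call. = FALSE)
  }
  targets <- intersect(targets, rownames(x))
  if (length(targets) < 1) {
    stop("No target present in the matrix.", call. = FALSE)
  }
  reg_row <- x[regulator, ]
  if (stats::sd(reg_row) == 0) {
    out <- NA_real_
    attr(out, "n_used") <- 0L
    attr(out, "n_skipped") <- length(targets)
    return(out)
  }
  tmat <- x[targets, , drop = FALSE]
  usable <- apply(tmat, 1, stats::sd) > 0
  r <- if (any(usable)) {
    as.numeric(stats::cor(reg_row, t(tmat[usable, , drop = FALSE])))
  } else {
    numeric(0)
  }
  out <- if (length(r)) mean(r) else NA_real_
  attr(out, "n_used") <- sum(usable)
  attr(out, "n_skipped") <- sum(!usable)
  out
}

# Correlation-weighted running-sum statistic: signed maximum deviation of
# the running sum over the sorted test list, hits stepping by w/sum(w).
weighted_es <- function(hit_pos, weights, n) {
  nh <- length(hit_pos)
  steps <- rep(-1 / (n - nh), n)
  tot <- sum(weights)
  steps[hit_pos] <- if (tot > 0) weights / tot else 1 / nh
  rs <- cumsum(steps)
  rs[es_extremum(rs)]
}

#' Prioritize transcriptional regulators (REGGAE-style)
#'
#' For each regulator in the interaction table with at least `min_targets`
#' targets inside the sorted test list, computes a correlation-weighted
#' running-sum enrichment of its targets within the list: hit increments
#' are proportional to `|Pearson r(regulator, target)|` over the matrix
#' samples (uniform fallback when all correlations are zero), miss
#' decrements uniform, statistic = signed maximum deviation. Significance
#' comes from `n_perm` membership permutations (weights reassigned to
#' random list positions; add-one estimator, two-sided on `|statistic|`),
#' adjusted by Benjamini-Hochberg across tested regulators. The
#' activator/repressor role follows the sign of the (signed) mean
#' regulator-target correlation.
#'
#' @param rti A `tk_rti` interaction table.
#' @param test_list A tibble `gene`, `score` sorted descending — typically
#'   the most upregulated genes of a contrast.
#' @param m A `tk_expr` expression matrix containing regulator and target
#'   rows.
#' @param min_targets Minimum targets inside the test list (default 5).
#' @param n_perm Membership permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `tk_regulators` with columns `regulator`,
#'   `n_targets_in_list`, `statistic`, `p_raw`, `p_adj`,
#'   `mean_correlation`, `role` (`activator`/`repressor`/`undetermined`),
#'   sorted by `p_raw` then regulator; attribute `excluded` records
#'   regulators not tested and why.
#' @export
reggae_analyze <- function(rti, test_list, m, min_targets = 5,
                           n_perm = 1000, seed = 42) {
  stopifnot(min_targets >= 2)
  test_list <- as_ranked_list(test_list)
  x <- expr_values(m)
  n <- nrow(test_list)
  regulators <- sort(unique(rti$regulator))
  rows <- list()
  excluded <- list()
  note_excluded <- function(reg, reason) {
    excluded[[length(excluded) + 1]] <<-
      tibble::tibble(regulator = reg, reason = reason)
  }
  stats_list <- withr::with_seed(seed, {
    purrr::map(regulators, function(reg) {
      targets <- rti$target[rti$regulator == reg]
      in_list <- intersect(targets, test_list$gene)
      if (length(in_list) < min_targets) {
        note_excluded(reg, "too_few_targets_in_list")
        return(NULL)
      }
      if (!reg %in% rownames(x)) {
        note_excluded(reg, "regulator_not_in_matrix")
        return(NULL)
      }
      in_mat <- intersect(in_list, rownames(x))
      if (length(in_mat) == 0) {
        note_excluded(reg, "no_target_in_matrix")
        return(NULL)
      }
      mc <- mean_target_correlation(m, reg, in_mat)
      # weights per target in the list; targets without a usable
      # correlation contribute weight 0
      reg_row <- x[reg, ]
      w <- vapply(in_list, function(tg) {
        if (!tg %in% rownames(x)) {
          return(0)
        }
        row <- x[tg, ]
        if (stats::sd(row) == 0 || stats::sd(reg_row) == 0) {
          return(0)
        }
        abs(stats::cor(reg_row, row))
      }, numeric(1))
      hit_pos <- sort(match(in_list, test_list$gene))
      w <- w[order(match(in_list, test_list$gene))]
      obs <- weighted_es(hit_pos, w, n)
      nh <- length(hit_pos)
      null <- vapply(seq_len(n_perm), function(b) {
        weighted_es(sort(sample.int(n, nh)), sample(w), n)
      }, numeric(1))
      p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
      role <- if (is.na(mc) || mc == 0) {
        "undetermined"
      } else if (mc > 0) {
        "activator"
      } else {
        "repressor"
      }
      tibble::tibble(
        regulator = reg,
        n_targets_in_list = nh,
        statistic = obs,
        p_raw = p,
        mean_correlation = as.numeric(mc),
        role = role
      )
    })
  })
  rows <- purrr::compact(stats_list)
  if (length(rows) == 0) {
    stop(
      "No regulator passed min_targets = ", min_targets, " (",
      length(regulators), " candidates, all excluded).",
      call. = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p_raw, "benjamini_hochberg")
  out <- out[, c(
    "regulator", "n_targets_in_list", "statistic", "p_raw", "p_adj",
    "mean_correlation", "role"
  )]
  out <- dplyr::arrange(out, .data$p_raw, .data$regulator)
  attr(out, "excluded") <- if (length(excluded)) {
    dplyr::bind_rows(excluded)
  } else {
    tibble::tibble(regulator = character(), reason = character())
  }
  class(out) <- c("tk_regulators", class(out))
  out
}

#' Split significant regulators into activators and repressors
#'
#' @param results A `tk_regulators` tibble from [reggae_analyze()].
#' @param alpha Adjusted-p significance cutoff in (0, 1).
#' @return A list with elements `activators` and `repressors`, each a
#'   tibble sorted by `p_adj` ascending. Significant regulators with
#'   undetermined role appear in neither list.
#' @export
split_roles <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  sig <- dplyr::filter(results, .data$p_adj <= alpha)
  list(
    activators = dplyr::arrange(
      dplyr::filter(sig, .data$role == "activator"),
      .data$p_adj, .data$regulator
    ),
    repressors = dplyr::arrange(
      dplyr::filter(sig, .data$role == "repressor"),
      .data$p_adj, .data$regulator
    )
  )
}
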