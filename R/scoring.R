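# Library-size normalization, signature scoring with per-cluster mean
# z-scores, cell-cycle scoring and phase assignment, tertile stratification.

#' Library-size normalize and log-transform a count matrix
#'
#' Scales each cell's counts to a fixed total (default 10,000) and applies
#' `log(1 + x)`, the standard normalization for UMI count matrices.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse),
#'   non-negative counts.
#' @param scale_factor target per-cell total.
#' @return A dgCMatrix of normalized values with the input dimnames.
#' @export
normalize_library <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop(
      sprintf(
        "cell(s) with zero total counts cannot be normalized: %s",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  norm <- Matrix::t(Matrix::t(counts) / totals) * scale_factor
  methods::as(log1p(norm), "CsparseMatrix")
}

# z-score with the zero-variance case defined as 0 rather than NaN
.zscore <- function(x, tol = 1e-12) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Score cells for a gene signature
#'
#' The per-cell signature value is the mean normalized (library-size scaled,
#' log-transformed) expression of the signature genes present in the matrix;
#' it is then z-scored across all cells. Genes absent from the matrix are
#' dropped with a warning; if no signature gene is present this is an error.
#' A constant signature yields z-scores of exactly 0 for every cell.
#'
#' @param expr normalized genes x cells matrix (see [normalize_library()]),
#'   or raw counts with `normalize = TRUE`.
#' @param genes character vector of signature gene ids.
#' @param set_name label stored with the scores.
#' @param normalize apply [normalize_library()] first.
#' @return A tibble `cell_id, set_name, score, zscore`.
#' @export
score_signature <- function(expr, genes, set_name = "signature",
                            normalize = FALSE) {
  if (normalize) expr <- normalize_library(expr)
  present <- intersect(genes, rownames(expr))
  absent <- setdiff(genes, rownames(expr))
  if (length(present) == 0L) {
    stop(sprintf("none of the %d signature genes are in the matrix.",
      length(genes)
    ), call. = FALSE)
  }
  if (length(absent) > 0L) {
    warning(sprintf(
      "%d signature gene(s) absent from the matrix and dropped: %s",
      length(absent), paste(utils::head(absent, 5), collapse = ", ")
    ))
  }
  score <- Matrix::colMeans(expr[present, , drop = FALSE])
  tibble::tibble(
    cell_id = colnames(expr),
    set_name = set_name,
    score = as.numeric(score),
    zscore = .zscore(as.numeric(score))
  )
}

#' Per-cluster mean z-scores of a signature
#'
#' Aggregates [score_signature()] output into the per-cluster mean z-score
#' values displayed in signature heatmaps.
#'
#' @param scores tibble from [score_signature()] (or rows of several sets).
#' @param meta per-cell metadata with `cell_id` and the cluster column.
#' @param cluster_col metadata column holding cluster labels.
#' @return A tibble `set_name, cluster, mean_zscore, n_cells`.
#' @export
cluster_signature_means <- function(scores, meta, cluster_col = "cluster_high") {
  meta <- tibble::as_tibble(meta)
  if (!cluster_col %in% names(meta)) {
    stop(sprintf("`meta` lacks column `%s`.", cluster_col), call. = FALSE)
  }
  scores |>
    dplyr::inner_join(
      meta[, c("cell_id", cluster_col)],
      by = "cell_id"
    ) |>
    dplyr::group_by(.data$set_name, cluster = .data[[cluster_col]]) |>
    dplyr::summarise(
      mean_zscore = mean(.data$zscore),
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Heatmap of per-cluster signature mean z-scores
#'
#' @param cluster_means tibble from [cluster_signature_means()].
#' @return A ggplot tile plot (signatures x clusters).
#' @export
plot_signature_heatmap <- function(cluster_means) {
  ggplot2::ggplot(
    cluster_means,
    ggplot2::aes(x = .data$cluster, y = .data$set_name, fill = .data$mean_zscore)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "cluster", y = NULL, fill = "mean z-score")
}

#' UMI-fraction cell-cycle score
#'
#' The cycle score of a cell is the fraction of its total UMIs that fall in
#' cell-cycle genes: `sum(counts[cc_genes, cell]) / sum(counts[, cell])`,
#' a value in [0, 1]. Computed on raw counts, not normalized values.
#'
#' @param counts genes x cells raw count matrix.
#' @param cc_genes character vector of cell-cycle gene ids.
#' @return A tibble `cell_id, cycle_score`.
#' @export
cell_cycle_score <- function(counts, cc_genes) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop(
      sprintf(
        "cell(s) with zero total UMIs have no defined cycle score: %s",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  present <- intersect(cc_genes, rownames(counts))
  cc <- if (length(present) == 0L) {
    rep(0, ncol(counts))
  } else {
    Matrix::colSums(counts[present, , drop = FALSE])
  }
  tibble::tibble(
    cell_id = colnames(counts),
    cycle_score = as.numeric(cc / totals)
  )
}

#' Module score for a gene set against an expression-matched background
#'
#' Mean normalized expression of the gene set minus the mean of an
#' expression-matched control: for each module gene, the `ctrl_per_gene`
#' non-module genes closest in overall mean expression serve as its
#' controls, and the per-gene control means are averaged. Matching the
#' background on expression keeps the score of a cell without module
#' activity near zero, so the fixed 0.1 phase threshold of [assign_phase()]
#' is meaningful. The selection is deterministic. Used for the S-phase and
#' G2/M scores.
#'
#' @param expr normalized genes x cells matrix.
#' @param genes gene ids of the module.
#' @param ctrl_per_gene control genes matched per module gene.
#' @return A named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, genes, ctrl_per_gene = 10L) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L) {
    stop("no module gene present in the matrix.", call. = FALSE)
  }
  pool <- setdiff(rownames(expr), present)
  if (length(pool) == 0L) {
    stop("no background genes available outside the module.", call. = FALSE)
  }
  avg <- Matrix::rowMeans(expr)
  rk <- rank(avg, ties.method = "first")
  names(rk) <- rownames(expr)
  # per module gene, the controls closest in overall expression; the per-gene
  # control means are averaged so the null expectation of the score is ~0
  ctrl_means <- vapply(present, function(g) {
    nb <- pool[order(abs(rk[pool] - rk[g]))][
      seq_len(min(ctrl_per_gene, length(pool)))
    ]
    Matrix::colMeans(expr[nb, , drop = FALSE])
  }, numeric(ncol(expr)))
  fg_mean <- Matrix::colMeans(expr[present, , drop = FALSE])
  bg_mean <- if (is.matrix(ctrl_means)) rowMeans(ctrl_means) else mean(ctrl_means)
  stats::setNames(as.numeric(fg_mean - bg_mean), colnames(expr))
}

#' Assign cell-cycle phase from S and G2/M scores
#'
#' A cell is in S phase when its S score is greater than 0.1 and greater
#' than its G2/M score; in G2/M phase when the G2/M score is greater than
#' 0.1 and greater than the S score; otherwise it is labelled `other`.
#' Both comparisons are strict, so an exact tie (or both scores at or below
#' 0.1) yields `other`.
#'
#' @param s_score,g2m_score numeric vectors of equal length; must be finite.
#' @return Character vector in `c("S", "G2M", "other")`.
#' @examples
#' assign_phase(c(0.2, 0.09, 0.3), c(0.05, 0.09, 0.3))
#' @export
assign_phase <- function(s_score, g2m_score) {
  if (length(s_score) != length(g2m_score)) {
    stop("score vectors must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(s_score)) || any(!is.finite(g2m_score))) {
    stop("phase scores must be finite.", call. = FALSE)
  }
  dplyr::case_when(
    s_score > 0.1 & s_score > g2m_score ~ "S",
    g2m_score > 0.1 & g2m_score > s_score ~ "G2M",
    .default = "other"
  )
}

#' Cell-cycle scoring and phase assignment in one step
#'
#' @param counts genes x cells raw count matrix.
#' @param s_genes,g2m_genes phase gene sets.
#' @param cc_genes combined cell-cycle set for the UMI-fraction score
#'   (defaults to the union of `s_genes` and `g2m_genes`).
#' @param scale_factor passed to [normalize_library()].
#' @return A tibble `cell_id, cycle_score, s_score, g2m_score, phase`.
#' @export
score_cell_cycle <- function(counts, s_genes, g2m_genes,
                             cc_genes = union(s_genes, g2m_genes),
                             scale_factor = 1e4) {
  expr <- normalize_library(counts, scale_factor)
  cyc <- cell_cycle_score(counts, cc_genes)
  s <- module_score(expr, s_genes)
  g2m <- module_score(expr, g2m_genes)
  cyc$s_score <- unname(s[cyc$cell_id])
  cyc$g2m_score <- unname(g2m[cyc$cell_id])
  cyc$phase <- assign_phase(cyc$s_score, cyc$g2m_score)
  cyc
}

#' Tertile stratification of scored patients
#'
#' Sorts patients by a signature score and returns the top and bottom
#' `fraction` of the cohort (`floor(n * fraction)` patients each; at
#' `fraction = 0.33` a cohort of 279 gives groups of 92). Ties are broken by
#' ascending `patient_id`, so group membership is deterministic; the middle
#' of the cohort is excluded.
#'
#' @param records tibble with `patient_id` and a score column.
#' @param score_col name of the score column.
#' @param fraction fraction per tail, in (0, 0.5].
#' @return The input tibble with a `group` column (`"top"`, `"bottom"`,
#'   `"middle"`), ordered as input.
#' @examples
#' df <- tibble::tibble(patient_id = sprintf("P%03d", 1:279), score = rnorm(279))
#' table(stratify_patients(df)$group)
#' @export
stratify_patients <- function(records, score_col = "score", fraction = 0.33) {
  records <- tibble::as_tibble(records)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
    fraction <= 0 || fraction > 0.5) {
    stop("`fraction` must be in (0, 0.5].", call. = FALSE)
  }
  if (!score_col %in% names(records)) {
    stop(sprintf("score column `%s` not found.", score_col), call. = FALSE)
  }
  s <- records[[score_col]]
  if (any(!is.finite(s))) stop("scores must be finite.", call. = FALSE)
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 patients to stratify.", call. = FALSE)
  k <- floor(n * fraction)
  ord <- order(s, records$patient_id) # ascending; one consistent ordering
  group <- rep("middle", n)
  group[ord[seq_len(k)]] <- "bottom"
  group[ord[seq.int(n - k + 1L, n)]] <- "top"
  records$group <- group
  records
}
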