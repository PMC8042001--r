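# Cell- and chain-level quality control: doublet budget, expression filters,
# single-productive-IGH selection, BCR/TCR double-positive removal.

#' Doublet exclusion budget from detected cell count
#'
#' Computes the number of barcodes to exclude as putative multiplets for a
#' library with `n` detected cells, using the linear-fit budget
#' `x = (0.000879 n + 0.702) * 0.01 * n`. The exact (pre-floor) value is kept
#' alongside the integer budget: fractional cells cannot be excluded, so the
#' budget is floored, which is conservative.
#'
#' @param n detected cell count(s); non-negative integers. Vectorized.
#' @return A tibble with columns `n_cells`, `x_exact` (the raw formula value)
#'   and `x_exclude` (`floor(x_exact)`).
#' @examples
#' doublet_exclusion_count(c(0, 2000, 10000))
#' @export
doublet_exclusion_count <- function(n) {
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != round(n))) {
    stop("`n` must contain non-negative integer cell counts.", call. = FALSE)
  }
  x <- (0.000879 * n + 0.702) * 0.01 * n
  tibble::tibble(
    n_cells = as.integer(n),
    x_exact = x,
    x_exclude = as.integer(floor(x))
  )
}

#' Exclude the top-scoring putative doublets
#'
#' Removes the `x` cells with the highest per-cell doublet score (for
#' example a pANN-style score computed upstream). Ties at the cut are broken
#' by ascending `cell_id`, so the retained set is deterministic.
#'
#' @param meta per-cell metadata with a `cell_id` column.
#' @param scores named numeric vector of per-cell scores, or the name of a
#'   column of `meta` holding them. Every cell must be scored.
#' @param x number of cells to exclude (for example
#'   `doublet_exclusion_count(nrow(meta))$x_exclude`).
#' @return A list with `retained` (tibble) and `excluded` (tibble with
#'   `cell_id` and `score`).
#' @examples
#' meta <- tibble::tibble(cell_id = letters[1:5])
#' exclude_top_scored(meta, stats::setNames(1:5, letters[1:5]), x = 2)
#' @export
exclude_top_scored <- function(meta, scores, x) {
  meta <- tibble::as_tibble(meta)
  if (is.character(scores) && length(scores) == 1L) {
    if (!scores %in% names(meta)) {
      stop(sprintf("score column `%s` not found.", scores), call. = FALSE)
    }
    sc <- meta[[scores]]
    names(sc) <- meta$cell_id
    scores <- sc
  }
  if (!all(meta$cell_id %in% names(scores))) {
    missing <- setdiff(meta$cell_id, names(scores))
    stop(
      sprintf(
        "missing doublet scores for %d cell(s), e.g. %s",
        length(missing), missing[1]
      ),
      call. = FALSE
    )
  }
  if (x < 0 || x > nrow(meta)) {
    stop("`x` must be between 0 and the number of cells.", call. = FALSE)
  }
  s <- scores[meta$cell_id]
  if (anyNA(s)) stop("doublet scores must be non-missing.", call. = FALSE)
  ord <- order(-s, meta$cell_id)
  drop_idx <- ord[seq_len(x)]
  excluded <- tibble::tibble(
    cell_id = meta$cell_id[drop_idx],
    score = unname(s[drop_idx])
  )
  retained <- if (x == 0L) meta else meta[-drop_idx, , drop = FALSE]
  list(retained = retained, excluded = excluded)
}

#' Expression-level cell filters
#'
#' Retains cells with `min_genes <= n_genes <= max_genes` and
#' `mito_fraction <= max_mito`. The exclusion rules are strict ("fewer than
#' 200 or more than 5000 detected genes", "more than 50% mitochondrial
#' UMIs"), so boundary cells are retained.
#'
#' @param meta per-cell metadata with `n_genes` and `mito_fraction` columns.
#' @param min_genes,max_genes retained range of detected genes (inclusive).
#' @param max_mito maximum retained mitochondrial UMI fraction (inclusive).
#' @return A list with `retained` (tibble) and `rejected` (tibble with
#'   `cell_id` and `reason` in `low_genes`, `high_genes`, `high_mito`).
#'   `nrow(retained) + nrow(rejected)` always equals `nrow(meta)`.
#' @examples
#' meta <- tibble::tibble(
#'   cell_id = c("a", "b"), n_genes = c(200L, 199L),
#'   mito_fraction = c(0.5, 0.1)
#' )
#' qc_filter_cells(meta)
#' @export
qc_filter_cells <- function(meta, min_genes = 200, max_genes = 5000,
                            max_mito = 0.5) {
  meta <- tibble::as_tibble(meta)
  needed <- c("cell_id", "n_genes", "mito_fraction")
  if (!all(needed %in% names(meta))) {
    stop("`meta` must have cell_id, n_genes and mito_fraction columns.",
      call. = FALSE
    )
  }
  reason <- dplyr::case_when(
    meta$n_genes < min_genes ~ "low_genes",
    meta$n_genes > max_genes ~ "high_genes",
    meta$mito_fraction > max_mito ~ "high_mito",
    .default = NA_character_
  )
  list(
    retained = meta[is.na(reason), , drop = FALSE],
    rejected = tibble::tibble(
      cell_id = meta$cell_id[!is.na(reason)],
      reason = reason[!is.na(reason)]
    )
  )
}

# Decide the productive-IGH outcome for one cell's UMI counts, strict 10-fold
# rule: the dominant contig is kept only if top > 10 * second.
.igh_decision <- function(umis) {
  if (length(umis) == 1L) {
    return("keep")
  }
  s <- sort(umis, decreasing = TRUE)
  if (s[1] > 10 * s[2]) "keep" else "multi_productive"
}

#' Select a single productive IGH per cell
#'
#' Implements the dominant-chain rule for cells with multiple productive IGH
#' contigs: the most abundant contig is kept only when its UMI count is more
#' than 10-fold that of the second most abundant ("more than" read strictly,
#' so a 50-vs-5 cell is rejected while 55-vs-5 is kept). With three or more
#' productive contigs only the top two enter the ratio test. Non-productive
#' contigs are ignored. Cells failing the rule, and cells with no productive
#' IGH, are rejected.
#'
#' @param records contig-level tibble (AIRR columns) for one or many cells;
#'   must include `cell_id`, `locus`, `productive`, `duplicate_count`.
#' @return A list with `kept` (one IGH row per retained cell; ties within a
#'   cell broken deterministically by descending UMI then sequence) and
#'   `rejected` (tibble `cell_id`, `reason` in `multi_productive`,
#'   `none_productive`).
#' @examples
#' x <- tibble::tibble(
#'   cell_id = "c1", locus = "IGH", productive = TRUE,
#'   duplicate_count = c(55L, 5L), sequence = c("AA", "CC")
#' )
#' select_single_productive_igh(x)$kept
#' @export
select_single_productive_igh <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    stop("`records` must contain at least one contig.", call. = FALSE)
  }
  igh <- records[records$locus == "IGH", , drop = FALSE]
  prod <- igh[igh$productive, , drop = FALSE]
  all_cells <- unique(records$cell_id)

  if (nrow(prod) == 0L) {
    return(list(
      kept = prod,
      rejected = tibble::tibble(
        cell_id = all_cells, reason = "none_productive"
      )
    ))
  }
  seq_col <- if ("sequence" %in% names(prod)) prod$sequence else ""
  ord <- order(prod$cell_id, -prod$duplicate_count, seq_col)
  prod <- prod[ord, , drop = FALSE]
  decisions <- prod |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      outcome = .igh_decision(.data$duplicate_count),
      .groups = "drop"
    )
  keep_cells <- decisions$cell_id[decisions$outcome == "keep"]
  kept <- prod[!duplicated(prod$cell_id) & prod$cell_id %in% keep_cells, ,
    drop = FALSE
  ]
  rejected <- tibble::tibble(
    cell_id = decisions$cell_id[decisions$outcome != "keep"],
    reason = decisions$outcome[decisions$outcome != "keep"]
  )
  no_prod <- setdiff(all_cells, prod$cell_id)
  if (length(no_prod) > 0L) {
    rejected <- dplyr::bind_rows(
      rejected,
      tibble::tibble(cell_id = no_prod, reason = "none_productive")
    )
  }
  list(kept = kept, rejected = dplyr::arrange(rejected, .data$cell_id))
}

#' Flag BCR/TCR double-positive barcodes
#'
#' A barcode is TCR-positive only when both a TRA and a TRB contig were
#' assembled; it is BCR-positive when at least one IGH contig was assembled.
#' Barcodes positive for both are flagged as B/T doublets and removed from
#' the B-cell set before subgrouping. A barcode with IGH plus TRA alone (or
#' TRB alone) is retained.
#'
#' @param records contig-level tibble with `cell_id` and `locus` columns
#'   (all contigs of all barcodes).
#' @return A list of tibbles: `b_cells` (cell_id of retained B cells),
#'   `flagged` (BCR/TCR double positives), and `summary` (per-barcode chain
#'   indicator table).
#' @examples
#' x <- tibble::tibble(
#'   cell_id = c("a", "a", "b", "b", "b"),
#'   locus = c("IGH", "TRA", "IGH", "TRA", "TRB")
#' )
#' flag_bcr_tcr_doublets(x)
#' @export
flag_bcr_tcr_doublets <- function(records) {
  records <- tibble::as_tibble(records)
  summary <- records |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      has_igh = any(.data$locus == "IGH"),
      has_tra = any(.data$locus == "TRA"),
      has_trb = any(.data$locus == "TRB"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bcr_positive = .data$has_igh,
      tcr_positive = .data$has_tra & .data$has_trb
    )
  list(
    b_cells = summary[summary$bcr_positive & !summary$tcr_positive, "cell_id"],
    flagged = summary[summary$bcr_positive & summary$tcr_positive, "cell_id"],
    summary = summary
  )
}

#' Run the full repertoire QC chain
#'
#' Convenience wrapper: expression-level cell filters, BCR/TCR
#' double-positive removal, then single-productive-IGH selection, returning
#' one clean IGH record per retained cell together with a combined rejection
#' log.
#'
#' @param records contig-level tibble (all loci).
#' @param meta per-cell metadata tibble.
#' @param min_genes,max_genes,max_mito passed to [qc_filter_cells()].
#' @return A list with `records` (one productive IGH per clean cell, with the
#'   metadata columns joined), `meta` (retained cells), and `rejections`
#'   (tibble `cell_id`, `reason`).
#' @export
repertoire_qc <- function(records, meta, min_genes = 200, max_genes = 5000,
                          max_mito = 0.5) {
  expr_qc <- qc_filter_cells(meta,
    min_genes = min_genes, max_genes = max_genes,
    max_mito = max_mito
  )
  keep_meta <- expr_qc$retained
  records <- records[records$cell_id %in% keep_meta$cell_id, , drop = FALSE]

  bt <- flag_bcr_tcr_doublets(records)
  flagged <- bt$flagged$cell_id
  records <- records[!records$cell_id %in% flagged, , drop = FALSE]
  records <- records[records$cell_id %in% bt$b_cells$cell_id, , drop = FALSE]

  sel <- select_single_productive_igh(records[records$locus == "IGH", ,
    drop = FALSE
  ])
  rejections <- dplyr::bind_rows(
    expr_qc$rejected,
    tibble::tibble(
      cell_id = flagged,
      reason = rep("bcr_tcr_doublet", length(flagged))
    ),
    sel$rejected
  )
  keep_meta <- keep_meta[keep_meta$cell_id %in% sel$kept$cell_id, , drop = FALSE]
  clean <- dplyr::left_join(
    sel$kept,
    keep_meta[, setdiff(
      names(keep_meta),
      setdiff(intersect(names(sel$kept), names(keep_meta)), "cell_id")
    )],
    by = "cell_id"
  )
  list(records = clean, meta = keep_meta, rejections = rejections)
}
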