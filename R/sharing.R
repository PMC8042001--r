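# Same-germline / same-sequence event counting between expression clusters
# and the per-10,000 normalization behind the sharing heatmaps.

# Unordered pairs within each level of `key`, returned as a two-column index
# matrix into the record order.
.pairs_within <- function(key) {
  groups <- split(seq_along(key), key)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  do.call(rbind, lapply(groups, function(idx) t(utils::combn(idx, 2L))))
}

#' Count clonal-sharing events between expression clusters
#'
#' Enumerates unordered cell pairs that share a BCR lineage and attributes
#' each pair to a cluster-pair cell of a compartment-group matrix. Two modes:
#' `same_germline` pairs cells of the same clone (same inferred germline
#' rearrangement); `same_sequence` pairs cells whose full observed IGH
#' nucleotide sequences are identical. Pairs are grouped by compartment:
#' `TNBC` when both cells come from tumor samples, `PBMC` when both come
#' from blood, `mixed` otherwise.
#'
#' Cluster sizes `n_a`/`n_b` (used by [normalize_sharing()]) are counted
#' within the pair's compartment group: tumor cell counts per cluster for the
#' TNBC matrix, blood counts for the PBMC matrix. The mixed-group matrix is
#' bipartite — `cluster_a` is always the tumor-side cluster (sized by tumor
#' cells) and `cluster_b` the blood-side cluster (sized by blood cells).
#' Within-compartment matrices are symmetric, with within-cluster pairs on
#' the diagonal.
#'
#' @param records one productive IGH row per cell with `cell_id`,
#'   `compartment`, and `clone_id` (for `same_germline`) or `sequence` (for
#'   `same_sequence`).
#' @param meta per-cell metadata with `cell_id`, `compartment`, and cluster
#'   labels.
#' @param mode `"same_germline"` or `"same_sequence"`.
#' @param resolution `"low"` or `"high"`: which cluster labels to use
#'   (`cluster_low` / `cluster_high` columns of `meta`).
#' @return An object of class `sharing_events`: a long tibble with one row
#'   per (group, cluster_a, cluster_b) combination carrying columns `mode`,
#'   `group`, `cluster_a`, `cluster_b`, `n_events`, `n_a`, `n_b`, including
#'   zero rows for unobserved combinations, plus attributes `clusters` and
#'   `resolution`. Pass to [normalize_sharing()], [sharing_matrix()] or
#'   [ggplot2::autoplot()].
#' @export
count_sharing_events <- function(records, meta,
                                 mode = c("same_germline", "same_sequence"),
                                 resolution = c("low", "high")) {
  mode <- match.arg(mode)
  resolution <- match.arg(resolution)
  cluster_col <- paste0("cluster_", resolution)
  records <- tibble::as_tibble(records)
  meta <- tibble::as_tibble(meta)
  if (!cluster_col %in% names(meta)) {
    stop(sprintf("`meta` lacks a %s column.", cluster_col), call. = FALSE)
  }

  idx <- match(records$cell_id, meta$cell_id)
  cluster <- meta[[cluster_col]][idx]
  unlabeled <- records$cell_id[is.na(cluster)]
  if (length(unlabeled) > 0L) {
    stop(
      sprintf(
        "%d cell(s) lack a cluster label at %s resolution, e.g.: %s",
        length(unlabeled), resolution,
        paste(utils::head(unlabeled, 5), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  compartment <- records$compartment

  key <- switch(mode,
    same_germline = {
      if (!"clone_id" %in% names(records)) {
        stop("mode 'same_germline' needs a clone_id column (run assign_clones()).",
          call. = FALSE
        )
      }
      records$clone_id
    },
    same_sequence = {
      if (!"sequence" %in% names(records)) {
        stop("mode 'same_sequence' needs a `sequence` column.", call. = FALSE)
      }
      records$sequence
    }
  )

  pairs <- .pairs_within(key)
  clusters <- sort(unique(meta[[cluster_col]]))
  # cluster sizes per compartment, over all labeled cells in the metadata
  sizes <- meta |>
    dplyr::count(.data$compartment, .data[[cluster_col]]) |>
    stats::setNames(c("compartment", "cluster", "n"))
  size_of <- function(comp, cl) {
    m <- sizes$n[sizes$compartment == comp & sizes$cluster == cl]
    if (length(m) == 0L) 0L else m
  }

  grid <- tidyr::expand_grid(
    group = c("TNBC", "PBMC", "mixed"),
    cluster_a = clusters, cluster_b = clusters
  )
  # within-compartment matrices are unordered: keep cluster_a <= cluster_b
  grid <- grid[grid$group == "mixed" |
    grid$cluster_a <= grid$cluster_b, , drop = FALSE]

  if (nrow(pairs) > 0L) {
    c1 <- cluster[pairs[, 1L]]
    c2 <- cluster[pairs[, 2L]]
    k1 <- compartment[pairs[, 1L]]
    k2 <- compartment[pairs[, 2L]]
    group <- ifelse(k1 == "tumor" & k2 == "tumor", "TNBC",
      ifelse(k1 == "blood" & k2 == "blood", "PBMC", "mixed")
    )
    # orient: within-compartment pairs by label order, mixed pairs
    # tumor-side first
    swap <- (group != "mixed" & c1 > c2) | (group == "mixed" & k1 == "blood")
    a <- ifelse(swap, c2, c1)
    b <- ifelse(swap, c1, c2)
    ev <- tibble::tibble(group = group, cluster_a = a, cluster_b = b) |>
      dplyr::count(.data$group, .data$cluster_a, .data$cluster_b,
        name = "n_events"
      )
  } else {
    ev <- tibble::tibble(
      group = character(), cluster_a = character(),
      cluster_b = character(), n_events = integer()
    )
  }

  out <- dplyr::left_join(
    grid, ev,
    by = c("group", "cluster_a", "cluster_b")
  )
  out$n_events[is.na(out$n_events)] <- 0L
  comp_a <- ifelse(out$group == "PBMC", "blood", "tumor")
  comp_b <- ifelse(out$group == "TNBC", "tumor", "blood")
  out$n_a <- mapply(size_of, comp_a, out$cluster_a)
  out$n_b <- mapply(size_of, comp_b, out$cluster_b)
  out <- tibble::as_tibble(out)
  out$mode <- mode
  out <- out[, c(
    "mode", "group", "cluster_a", "cluster_b", "n_events", "n_a", "n_b"
  )]
  structure(out,
    class = c("sharing_events", class(out)),
    clusters = clusters, resolution = resolution
  )
}

#' Normalize sharing-event counts by cluster sizes
#'
#' Applies the per-10,000 normalization
#' `n_normalized = (N / N_A) * (N / N_B) * 10000`, where `N` is the event
#' count of a cluster pair and `N_A`, `N_B` are the cell counts of the two
#' clusters in the pair's compartment group (the diagonal uses the same
#' cluster size on both sides). Pairs with zero events normalize to zero
#' regardless of sizes; a cluster with zero cells and zero events yields a
#' masked (`NA`) entry rather than a division by zero, and a zero-size
#' cluster with nonzero events is a data inconsistency and errors.
#'
#' @param events a `sharing_events` tibble from [count_sharing_events()].
#' @return The same object with an `n_normalized` column added.
#' @examples
#' ev <- tibble::tibble(
#'   mode = "same_germline", group = "TNBC", cluster_a = "C1",
#'   cluster_b = "C2", n_events = 4L, n_a = 40L, n_b = 20L
#' )
#' normalize_sharing(ev)$n_normalized # (4/40)*(4/20)*10000 = 200
#' @export
normalize_sharing <- function(events) {
  bad <- events$n_events > 0L & (events$n_a == 0L | events$n_b == 0L)
  if (any(bad)) {
    stop(
      sprintf(
        "%d cluster pair(s) have events but a zero-size cluster; data inconsistent.",
        sum(bad)
      ),
      call. = FALSE
    )
  }
  n <- events$n_events
  nn <- ifelse(
    n == 0L,
    ifelse(events$n_a == 0L | events$n_b == 0L, NA_real_, 0),
    (n / events$n_a) * (n / events$n_b) * 10000
  )
  events$n_normalized <- nn
  events
}

#' Cast sharing events to a cluster-by-cluster matrix
#'
#' @param events a `sharing_events` tibble (normalized or raw).
#' @param group one of `"TNBC"`, `"PBMC"`, `"mixed"`.
#' @param value which column to place in the matrix cells.
#' @return A numeric matrix, clusters in rows and columns. Within-compartment
#'   groups give a symmetric matrix; for `"mixed"`, rows are tumor-side and
#'   columns blood-side clusters.
#' @export
sharing_matrix <- function(events, group = c("TNBC", "PBMC", "mixed"),
                           value = c("n_normalized", "n_events")) {
  group <- match.arg(group)
  value <- match.arg(value)
  if (!value %in% names(events)) {
    stop(sprintf("column `%s` not present; run normalize_sharing() first.",
      value
    ), call. = FALSE)
  }
  clusters <- attr(events, "clusters")
  if (is.null(clusters)) {
    clusters <- sort(unique(c(events$cluster_a, events$cluster_b)))
  }
  m <- matrix(0, length(clusters), length(clusters),
    dimnames = list(clusters, clusters)
  )
  sub <- events[events$group == group, , drop = FALSE]
  ia <- match(sub$cluster_a, clusters)
  ib <- match(sub$cluster_b, clusters)
  m[cbind(ia, ib)] <- sub[[value]]
  if (group != "mixed") {
    m[cbind(ib, ia)] <- sub[[value]]
  }
  m
}

#' Tidy sharing events
#'
#' @param x a `sharing_events` object.
#' @param ... unused.
#' @return The underlying long tibble.
#' @exportS3Method generics::tidy
tidy.sharing_events <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Heatmap of normalized clonal sharing between clusters
#'
#' @param object a `sharing_events` object (run through
#'   [normalize_sharing()] first for normalized values).
#' @param value column to display.
#' @param ... unused.
#' @return A ggplot object, one facet per compartment group.
#' @exportS3Method ggplot2::autoplot
autoplot.sharing_events <- function(object,
                                    value = c("n_normalized", "n_events"),
                                    ...) {
  value <- match.arg(value)
  if (!value %in% names(object)) {
    stop(sprintf("column `%s` not present; run normalize_sharing() first.",
      value
    ), call. = FALSE)
  }
  df <- tidy.sharing_events(object)
  # mirror the unordered within-compartment pairs so facets show full squares
  mirror <- df[df$group != "mixed" & df$cluster_a != df$cluster_b, ,
    drop = FALSE
  ]
  if (nrow(mirror) > 0L) {
    tmp <- mirror$cluster_a
    mirror$cluster_a <- mirror$cluster_b
    mirror$cluster_b <- tmp
    df <- dplyr::bind_rows(df, mirror)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$cluster_a, y = .data$cluster_b,
      fill = .data[[value]]
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(
      x = "cluster", y = "cluster", fill = value,
      title = sprintf("%s events", unique(df$mode))
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
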