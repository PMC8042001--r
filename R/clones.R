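# Clone calling by inferred germline identity, SHM and class-switch
# statistics, repertoire summaries, and public-clonotype matching.

#' Strip allele suffixes from V/D/J gene calls
#'
#' `"IGHV3*02"` becomes `"IGHV3"`. Clone keys compare gene usage, not allele
#' resolution, so alleles of the same gene must merge.
#'
#' @param call character vector of gene calls (NA allowed).
#' @return character vector of gene names.
#' @export
strip_allele <- function(call) {
  sub("\\*.*$", "", call)
}

# Canonical germline key for a record set. Absent D calls form their own key
# level ("<none>") so they never silently merge with resolved D genes other
# than each other.
.germline_key <- function(records, allele_resolution = FALSE) {
  v <- records$v_call
  d <- records$d_call
  j <- records$j_call
  if (!allele_resolution) {
    v <- strip_allele(v)
    d <- strip_allele(d)
    j <- strip_allele(j)
  }
  d[is.na(d) | d == ""] <- "<none>"
  paste(v, d, j, nchar(records$junction), sep = "|")
}

#' Assign cells to clones by shared inferred germline
#'
#' Two cells belong to the same clone when their IGH rearrangements have the
#' same V, D and J gene usage and the same junction length (junction
#' sequences may differ: clone identity keys on the inferred germline
#' rearrangement, not on the mutated sequence). Comparison is at gene level
#' by default, with allele suffixes stripped. Records lacking a D call merge
#' only with other records lacking a D call.
#'
#' @param records tibble with one post-QC productive IGH row per cell
#'   (`cell_id`, `v_call`, `d_call`, `j_call`, `junction`).
#' @param allele_resolution compare calls at allele level instead of gene
#'   level.
#' @return The input tibble with a `clone_id` column added (`CL000001`, ...,
#'   numbered in lexicographic key order so ids are deterministic).
#' @examples
#' x <- tibble::tibble(
#'   cell_id = c("a", "b", "c"),
#'   v_call = c("IGHV1*01", "IGHV1*02", "IGHV1*01"),
#'   d_call = c("IGHD2", "IGHD2", "IGHD2"),
#'   j_call = c("IGHJ4", "IGHJ4", "IGHJ5"),
#'   junction = c("TGTGCGAGA", "TGTAAAAGA", "TGTGCGAGA")
#' )
#' assign_clones(x)$clone_id # a and b share a clone, c does not
#' @export
assign_clones <- function(records, allele_resolution = FALSE) {
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$cell_id)) {
    dup <- records$cell_id[duplicated(records$cell_id)][1]
    stop(
      sprintf(
        "duplicate cell_id `%s`: assign_clones expects one IGH record per cell.",
        dup
      ),
      call. = FALSE
    )
  }
  key <- .germline_key(records, allele_resolution)
  ids <- match(key, sort(unique(key)))
  records$clone_id <- sprintf("CL%06d", ids)
  records
}

#' Summarise clones
#'
#' Per-clone membership, per-compartment sizes, and the mean somatic
#' hypermutation frequency over members (SHM frequency computed over V and J
#' segments only; see [add_shm_stats()]).
#'
#' @param records output of [assign_clones()]; if `mut_frequency` is absent
#'   it is computed with [add_shm_stats()].
#' @return A tibble with one row per clone: `clone_id`, `v_gene`, `d_gene`,
#'   `j_gene`, `junction_length`, `size`, `n_tumor`, `n_blood`,
#'   `mean_mut_frequency`, and a `cell_ids` list column.
#' @export
clone_table <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"clone_id" %in% names(records)) {
    stop("`records` must carry a clone_id column; run assign_clones() first.",
      call. = FALSE
    )
  }
  if (!"mut_frequency" %in% names(records)) {
    records <- add_shm_stats(records)
  }
  has_comp <- "compartment" %in% names(records)
  records |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      v_gene = strip_allele(.data$v_call[1]),
      d_gene = strip_allele(.data$d_call[1]),
      j_gene = strip_allele(.data$j_call[1]),
      junction_length = nchar(.data$junction[1]),
      size = dplyr::n(),
      n_tumor = if (has_comp) sum(.data$compartment == "tumor") else NA_integer_,
      n_blood = if (has_comp) sum(.data$compartment == "blood") else NA_integer_,
      mean_mut_frequency = mean(.data$mut_frequency),
      cell_ids = list(.data$cell_id),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$clone_id)
}

#' Somatic hypermutation statistics per record
#'
#' SHM number and frequency are computed over the V and J segments only: the
#' D segment and the junction are excluded because the inferred germline is
#' ambiguous there. `mut_count = v_mut_count + j_mut_count`;
#' `mut_frequency = mut_count / vj_aligned_length`.
#'
#' @param records tibble with `v_mut_count`, `j_mut_count`,
#'   `vj_aligned_length`.
#' @return The input with `mut_count` and `mut_frequency` columns added.
#' @examples
#' add_shm_stats(tibble::tibble(
#'   v_mut_count = 5L, j_mut_count = 1L, vj_aligned_length = 300L
#' ))
#' @export
add_shm_stats <- function(records) {
  records <- tibble::as_tibble(records)
  if (any(records$vj_aligned_length <= 0)) {
    stop("`vj_aligned_length` must be positive for every record.",
      call. = FALSE
    )
  }
  records$mut_count <- records$v_mut_count + records$j_mut_count
  records$mut_frequency <- records$mut_count / records$vj_aligned_length
  records
}

# c_call prefix -> isotype class
.isotype_class <- function(c_call) {
  dplyr::case_when(
    is.na(c_call) ~ "unknown",
    startsWith(c_call, "IGHM") ~ "IGM",
    startsWith(c_call, "IGHD") ~ "IGD",
    startsWith(c_call, "IGHG") ~ "IGG",
    startsWith(c_call, "IGHA") ~ "IGA",
    startsWith(c_call, "IGHE") ~ "IGE",
    .default = "unknown"
  )
}

#' Isotype class, class-switch and germline status per record
#'
#' `isotype_class` collapses constant-region calls to IGM/IGD/IGG/IGA/IGE
#' (subclass suffixes dropped); `switched` is TRUE for isotypes outside
#' IGM/IGD; `germline` is TRUE when the record carries zero V+J mutations
#' (an antigen-inexperienced receptor). Unknown isotypes get
#' `switched = FALSE` with `isotype_known = FALSE` so they can be excluded
#' from switch-rate summaries.
#'
#' @param records tibble with `c_call`, `v_mut_count`, `j_mut_count`.
#' @return The input with `isotype_class`, `isotype_known`, `switched`,
#'   `germline` columns added.
#' @export
add_bcr_status <- function(records) {
  records <- tibble::as_tibble(records)
  cls <- .isotype_class(records$c_call)
  records$isotype_class <- cls
  records$isotype_known <- cls != "unknown"
  records$switched <- records$isotype_known & !cls %in% c("IGM", "IGD")
  records$germline <- (records$v_mut_count + records$j_mut_count) == 0L
  records
}

#' Per-group repertoire summary
#'
#' For each group (compartment by default): isotype class fractions, the
#' germline fraction, the clonal fraction (cells belonging to clones of size
#' two or more, as a fraction of all cells), cell and clone counts.
#'
#' @param records output of [assign_clones()], with status columns added as
#'   needed.
#' @param group_by metadata column(s) to group by, e.g. `"compartment"` or
#'   `c("compartment", "sample_id")`.
#' @return A tibble with one row per group and columns `n_cells`, `n_clones`,
#'   `clonal_fraction`, `germline_fraction`, `switched_fraction`,
#'   `mean_mut_frequency`, and one `frac_<class>` column per observed
#'   isotype class.
#' @export
repertoire_summary <- function(records, group_by = "compartment") {
  records <- tibble::as_tibble(records)
  if (!"clone_id" %in% names(records)) records <- assign_clones(records)
  if (!"mut_frequency" %in% names(records)) records <- add_shm_stats(records)
  if (!"switched" %in% names(records)) records <- add_bcr_status(records)
  missing_groups <- setdiff(group_by, names(records))
  if (length(missing_groups) > 0L) {
    stop(sprintf("grouping column(s) not found: %s",
      paste(missing_groups, collapse = ", ")
    ), call. = FALSE)
  }

  records <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by)), .data$clone_id) |>
    dplyr::mutate(.clone_size_in_group = dplyr::n()) |>
    dplyr::ungroup()

  base <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_clones = dplyr::n_distinct(.data$clone_id),
      clonal_fraction = mean(.data$.clone_size_in_group >= 2L),
      germline_fraction = mean(.data$germline),
      switched_fraction = mean(.data$switched[.data$isotype_known]),
      mean_mut_frequency = mean(.data$mut_frequency),
      .groups = "drop"
    )
  iso <- records |>
    dplyr::count(
      dplyr::across(dplyr::all_of(group_by)), .data$isotype_class
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::mutate(frac = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(
      names_from = "isotype_class", values_from = "frac",
      names_prefix = "frac_", values_fill = 0
    )
  out <- dplyr::left_join(base, iso, by = group_by)
  if (nrow(out) == 0L) warning("no groups present; returning empty summary.")
  out
}

#' Clone-size distribution per group
#'
#' @param records output of [assign_clones()].
#' @param group_by metadata column(s) to group by.
#' @return A tibble `group..., clone_size, n_clones`, where `clone_size` is
#'   the number of member cells of the clone within the group.
#' @export
clone_size_distribution <- function(records, group_by = "compartment") {
  records <- tibble::as_tibble(records)
  records |>
    dplyr::count(
      dplyr::across(dplyr::all_of(group_by)), .data$clone_id,
      name = "clone_size"
    ) |>
    dplyr::count(
      dplyr::across(dplyr::all_of(group_by)), .data$clone_size,
      name = "n_clones"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_by, "clone_size"))))
}

#' Extract unique clonotypes
#'
#' A clonotype is the triple (V gene, J gene, CDRH3 amino-acid sequence);
#' it is the unit matched across cohorts when counting public clones.
#'
#' @param records tibble with `v_call`, `j_call` and `junction_aa` (used as
#'   the CDRH3 amino-acid sequence).
#' @return A deduplicated tibble `v_gene, j_gene, cdr3_aa`.
#' @export
extract_clonotypes <- function(records) {
  records <- tibble::as_tibble(records)
  out <- tibble::tibble(
    v_gene = strip_allele(records$v_call),
    j_gene = strip_allele(records$j_call),
    cdr3_aa = records$junction_aa
  )
  out <- out[!is.na(out$cdr3_aa) & nzchar(out$cdr3_aa), , drop = FALSE]
  dplyr::distinct(out)
}

#' Public-clone fraction against a reference repertoire
#'
#' A clonotype of the study repertoire is public when the identical
#' (V gene, J gene, CDRH3 amino acid) triple occurs in the reference
#' repertoire. The public-clone percentage is the number of shared unique
#' clonotypes divided by the number of unique study clonotypes. When
#' `other` is supplied, a chi-square test compares the public/non-public
#' counts of the two study cohorts (Pearson statistic, no continuity
#' correction unless requested).
#'
#' @param study,reference clonotype tibbles (`v_gene`, `j_gene`, `cdr3_aa`),
#'   e.g. from [extract_clonotypes()]. Deduplicated internally.
#' @param other optional second study cohort to compare against `study`.
#' @param correct logical; apply Yates continuity correction.
#' @return An object of class `public_clone_test`: a list with `shared_count`,
#'   `n_study`, `percentage` (0-100), and — when `other` is given — the 2x2
#'   `table` and `htest` from [stats::chisq.test()]. Has [tidy()] and
#'   [glance()] methods.
#' @export
public_clone_fraction <- function(study, reference, other = NULL,
                                  correct = FALSE) {
  study <- dplyr::distinct(tibble::as_tibble(study))
  reference <- dplyr::distinct(tibble::as_tibble(reference))
  if (nrow(study) == 0L) {
    stop("`study` contains no clonotypes; the percentage is undefined.",
      call. = FALSE
    )
  }
  keycols <- c("v_gene", "j_gene", "cdr3_aa")
  shared <- dplyr::inner_join(study, reference, by = keycols)
  res <- list(
    shared_count = nrow(shared),
    n_study = nrow(study),
    percentage = 100 * nrow(shared) / nrow(study)
  )
  if (!is.null(other)) {
    other <- dplyr::distinct(tibble::as_tibble(other))
    shared2 <- dplyr::inner_join(other, reference, by = keycols)
    tab <- matrix(
      c(
        nrow(shared), nrow(study) - nrow(shared),
        nrow(shared2), nrow(other) - nrow(shared2)
      ),
      nrow = 2,
      dimnames = list(
        c("public", "nonpublic"),
        c("study", "other")
      )
    )
    res$table <- tab
    res$htest <- stats::chisq.test(tab, correct = correct)
    res$other_shared_count <- nrow(shared2)
    res$other_n <- nrow(other)
    res$other_percentage <- 100 * nrow(shared2) / nrow(other)
  }
  structure(res, class = "public_clone_test")
}

#' @export
print.public_clone_test <- function(x, ...) {
  cat(sprintf(
    "Public clones: %d / %d unique clonotypes (%.2f%%)\n",
    x$shared_count, x$n_study, x$percentage
  ))
  if (!is.null(x$htest)) {
    cat(sprintf(
      "Chi-square vs second cohort: X^2 = %.3f, p = %.3g\n",
      unname(x$htest$statistic), x$htest$p.value
    ))
  }
  invisible(x)
}

#' Tidy a public-clone test
#'
#' @param x a `public_clone_test`.
#' @param ... unused.
#' @return One row per cohort with shared counts and percentages.
#' @exportS3Method generics::tidy
tidy.public_clone_test <- function(x, ...) {
  out <- tibble::tibble(
    cohort = "study",
    shared_count = x$shared_count,
    n_unique = x$n_study,
    percentage = x$percentage
  )
  if (!is.null(x$htest)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      cohort = "other",
      shared_count = x$other_shared_count,
      n_unique = x$other_n,
      percentage = x$other_percentage
    ))
  }
  out
}

#' Glance at a public-clone test
#'
#' @param x a `public_clone_test`.
#' @param ... unused.
#' @return A one-row tibble with the percentage and, if computed, the
#'   chi-square statistic and p-value.
#' @exportS3Method generics::glance
glance.public_clone_test <- function(x, ...) {
  tibble::tibble(
    shared_count = x$shared_count,
    n_study = x$n_study,
    percentage = x$percentage,
    statistic = if (is.null(x$htest)) NA_real_ else unname(x$htest$statistic),
    p_value = if (is.null(x$htest)) NA_real_ else x$htest$p.value
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
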