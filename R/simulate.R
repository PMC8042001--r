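# Synthetic paired repertoire + expression generator with planted ground truth.

# Fixed synthetic V/D/J gene dictionaries. Deliberately small so that clone
# keys have realistic collision structure; these are not real IMGT alleles.
.vdj_dictionary <- function() {
  list(
    v = paste0("IGHV", 1:20),
    d = paste0("IGHD", 1:6),
    j = paste0("IGHJ", 1:6)
  )
}

.iso_switched <- c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2", "IGHE")
.iso_switched_w <- c(0.35, 0.25, 0.10, 0.05, 0.15, 0.08, 0.02)
.iso_unswitched <- c("IGHM", "IGHD")
.iso_unswitched_w <- c(0.8, 0.2)

# Map the 13 high-resolution clusters onto the 4 low-resolution groups:
# naive (C1-C2), memory (C3-C10), plasma/germinal-center (C11-C12),
# CD14+ atypical (C13).
.cluster_low_of_high <- function(high) {
  idx <- as.integer(sub("^C", "", high))
  low <- character(length(idx))
  low[idx <= 2] <- "naive"
  low[idx >= 3 & idx <= 10] <- "memory"
  low[idx >= 11 & idx <= 12] <- "plasma"
  low[idx >= 13] <- "atypical"
  low
}

#' Configuration for the synthetic paired repertoire generator
#'
#' Builds a validated configuration object for [simulate_repertoire()],
#' [simulate_expression()] and [simulate_paired()]. Defaults emulate the
#' qualitative tumor-versus-blood contrasts seen in triple-negative breast
#' cancer B-cell repertoires: tumors carry more and larger clones, higher
#' somatic hypermutation (SHM), and a larger class-switched fraction than
#' matched peripheral blood.
#'
#' @param n_cells_per_sample cells simulated per sample.
#' @param n_samples_tumor,n_samples_blood number of tumor (TNBC) and blood
#'   (PBMC) samples. Samples are paired by index (TNBC1 with PBMC1, ...).
#' @param clonal_fraction_tumor,clonal_fraction_blood fraction of cells placed
#'   in clones of size >= 2, per compartment.
#' @param clone_size_distribution named numeric vector of probabilities over
#'   clone sizes >= 2 (names are the sizes).
#' @param shm_rate_tumor,shm_rate_blood expected mutations per aligned V+J
#'   nucleotide, per compartment.
#' @param p_switch_tumor,p_switch_blood probability a cell carries a
#'   class-switched (non-IGM/IGD) isotype.
#' @param p_doublet probability a barcode is a doublet (receives a second
#'   cell's contigs and expression).
#' @param p_multi_productive probability of a spurious second productive IGH
#'   contig with minor UMI support.
#' @param p_cross_compartment probability a tumor clone also recruits one cell
#'   from the paired blood sample (source of mixed-compartment lineage
#'   sharing).
#' @param p_identical_seq probability a non-founder clone member carries the
#'   founder's exact IGH sequence (source of same-sequence events).
#' @param p_tcr probability a B cell barcode also carries assembled TRA and
#'   TRB contigs (BCR/TCR double positivity).
#' @param umi_dominant_range,umi_minor_range integer ranges (length-2 vectors)
#'   for dominant and minor contig UMI counts.
#' @param n_genes number of genes in the expression matrix.
#' @param n_clusters_high,n_clusters_low number of high- and low-resolution
#'   cluster labels (13 and 4 by default).
#' @param min_total_umi floor on the per-cell expression total.
#' @param sig_effect log-scale mean shift planted for the signature gene set
#'   in its target cluster (0 disables the effect).
#' @param cc_effect multiplicative boost of cell-cycle gene expression in
#'   cycling cells.
#' @param seed integer random seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_cells_per_sample = 100, seed = 1)
#' @export
sim_config <- function(n_cells_per_sample = 500,
                       n_samples_tumor = 5,
                       n_samples_blood = 5,
                       clonal_fraction_tumor = 0.19,
                       clonal_fraction_blood = 0.07,
                       clone_size_distribution = c(
                         "2" = 0.50, "3" = 0.22, "4" = 0.12,
                         "5" = 0.08, "6" = 0.05, "8" = 0.03
                       ),
                       shm_rate_tumor = 0.02,
                       shm_rate_blood = 0.01,
                       p_switch_tumor = 0.60,
                       p_switch_blood = 0.30,
                       p_doublet = 0.01,
                       p_multi_productive = 0.02,
                       p_cross_compartment = 0.05,
                       p_identical_seq = 0.30,
                       p_tcr = 0.01,
                       umi_dominant_range = c(20L, 80L),
                       umi_minor_range = c(1L, 5L),
                       n_genes = 200,
                       n_clusters_high = 13,
                       n_clusters_low = 4,
                       min_total_umi = 500,
                       sig_effect = 1,
                       cc_effect = 8,
                       seed = 1L) {
  cfg <- list(
    n_cells_per_sample = n_cells_per_sample,
    n_samples_tumor = n_samples_tumor,
    n_samples_blood = n_samples_blood,
    clonal_fraction_tumor = clonal_fraction_tumor,
    clonal_fraction_blood = clonal_fraction_blood,
    clone_size_distribution = clone_size_distribution,
    shm_rate_tumor = shm_rate_tumor,
    shm_rate_blood = shm_rate_blood,
    p_switch_tumor = p_switch_tumor,
    p_switch_blood = p_switch_blood,
    p_doublet = p_doublet,
    p_multi_productive = p_multi_productive,
    p_cross_compartment = p_cross_compartment,
    p_identical_seq = p_identical_seq,
    p_tcr = p_tcr,
    umi_dominant_range = as.integer(umi_dominant_range),
    umi_minor_range = as.integer(umi_minor_range),
    n_genes = n_genes,
    n_clusters_high = n_clusters_high,
    n_clusters_low = n_clusters_low,
    min_total_umi = min_total_umi,
    sig_effect = sig_effect,
    cc_effect = cc_effect,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(
    "clonal_fraction_tumor", "clonal_fraction_blood",
    "p_switch_tumor", "p_switch_blood", "p_doublet", "p_multi_productive",
    "p_cross_compartment", "p_identical_seq", "p_tcr"
  )
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single probability in [0, 1].", p),
        call. = FALSE
      )
    }
  }
  counts <- c(
    "n_cells_per_sample", "n_samples_tumor", "n_samples_blood",
    "n_genes", "n_clusters_high", "n_clusters_low", "min_total_umi"
  )
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
      v != round(v)) {
      stop(sprintf("`%s` must be a single non-negative integer.", p),
        call. = FALSE
      )
    }
  }
  rates <- c("shm_rate_tumor", "shm_rate_blood", "sig_effect", "cc_effect")
  for (p in rates) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number.", p), call. = FALSE)
    }
  }
  if (cfg$shm_rate_tumor < 0 || cfg$shm_rate_blood < 0) {
    stop("SHM rates must be non-negative.", call. = FALSE)
  }
  csd <- cfg$clone_size_distribution
  sizes <- suppressWarnings(as.integer(names(csd)))
  if (is.null(names(csd)) || anyNA(sizes) || any(sizes < 2) ||
    any(!is.finite(csd)) || any(csd < 0) || sum(csd) <= 0) {
    stop("`clone_size_distribution` must be named by sizes >= 2 with non-negative weights.",
      call. = FALSE
    )
  }
  for (p in c("umi_dominant_range", "umi_minor_range")) {
    v <- cfg[[p]]
    if (length(v) != 2L || anyNA(v) || any(v < 1) || v[1] > v[2]) {
      stop(sprintf("`%s` must be a positive increasing integer range.", p),
        call. = FALSE
      )
    }
  }
  if (cfg$n_genes < 60) {
    stop("`n_genes` must be at least 60 (the planted gene sets use 50 genes).",
      call. = FALSE
    )
  }
  if (!is.finite(cfg$seed)) stop("`seed` must be a finite integer.", call. = FALSE)
  invisible(cfg)
}

.sample_range <- function(lo, hi, n) {
  x <- seq.int(lo, hi)
  x[sample.int(length(x), n, replace = TRUE)]
}

.random_dna <- function(n_seqs, len) {
  vapply(
    seq_len(n_seqs),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)
  )
}

.translate_nt <- function(nt) {
  vapply(nt, function(s) {
    paste(seqinr::translate(seqinr::s2c(tolower(s))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.mutate_dna <- function(seq, n_mut) {
  if (n_mut == 0L) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), min(n_mut, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Draw clone sizes until they cover n_clonal cells exactly, shrinking the last
# clone to fit (and folding a leftover single cell into the previous clone).
.draw_clone_sizes <- function(n_clonal, dist) {
  if (n_clonal < 2L) {
    return(integer(0))
  }
  sizes <- integer(0)
  total <- 0L
  choices <- as.integer(names(dist))
  w <- dist / sum(dist)
  while (total < n_clonal) {
    s <- sample(choices, 1L, prob = w)
    sizes <- c(sizes, s)
    total <- total + s
  }
  excess <- total - n_clonal
  if (excess > 0L) {
    last <- sizes[length(sizes)] - excess
    if (last >= 2L) {
      sizes[length(sizes)] <- last
    } else {
      sizes <- sizes[-length(sizes)]
      short <- n_clonal - sum(sizes)
      if (short > 0L) {
        if (length(sizes) > 0L && short == 1L) {
          sizes[length(sizes)] <- sizes[length(sizes)] + 1L
        } else if (short >= 2L) {
          sizes <- c(sizes, short)
        } else if (length(sizes) == 0L) {
          sizes <- integer(0)
        }
      }
    }
  }
  sizes
}

# One IGH record (one row) per (cell, lineage slot). `founder` rows define the
# clone's reference sequence copied by identical-sequence members.
.simulate_igh_for_clone <- function(cells, clone_id, compartment, cfg, dict,
                                    key = NULL) {
  n <- length(cells)
  if (is.null(key)) {
    key <- list(
      v = sample(dict$v, 1L),
      d = if (stats::runif(1) < 1 / 7) NA_character_ else sample(dict$d, 1L),
      j = sample(dict$j, 1L),
      len = sample(seq(30L, 75L, by = 3L), 1L)
    )
  }
  v_gene <- key$v
  d_gene <- key$d
  j_gene <- key$j
  junction_len <- key$len
  vj_len <- sample(270:330, 1L)
  germ_v_len <- round(vj_len * 0.8)
  germ <- .random_dna(1L, vj_len)
  germ_v <- substr(germ, 1L, germ_v_len)
  germ_j <- substr(germ, germ_v_len + 1L, vj_len)

  rate <- if (compartment == "tumor") cfg$shm_rate_tumor else cfg$shm_rate_blood
  p_sw <- if (compartment == "tumor") cfg$p_switch_tumor else cfg$p_switch_blood

  # allele suffixes vary within the clone; gene-level keys must merge them
  allele <- function(g) ifelse(is.na(g), NA_character_,
    paste0(g, sample(c("*01", "*02"), length(g), replace = TRUE))
  )

  n_mut <- stats::rpois(n, rate * vj_len)
  n_mut <- pmin(n_mut, vj_len)
  v_mut <- stats::rbinom(n, n_mut, germ_v_len / vj_len)
  j_mut <- n_mut - v_mut

  junction <- .random_dna(n, junction_len)
  seq_v <- character(n)
  seq_j <- character(n)
  for (i in seq_len(n)) {
    seq_v[i] <- .mutate_dna(germ_v, v_mut[i])
    seq_j[i] <- .mutate_dna(germ_j, j_mut[i])
  }
  copy <- rep(FALSE, n)
  if (n > 1L) {
    copy[-1L] <- stats::runif(n - 1L) < cfg$p_identical_seq
    junction[copy] <- junction[1L]
    seq_v[copy] <- seq_v[1L]
    seq_j[copy] <- seq_j[1L]
    v_mut[copy] <- v_mut[1L]
    j_mut[copy] <- j_mut[1L]
  }
  switched <- stats::runif(n) < p_sw
  c_call <- ifelse(
    switched,
    sample(.iso_switched, n, replace = TRUE, prob = .iso_switched_w),
    sample(.iso_unswitched, n, replace = TRUE, prob = .iso_unswitched_w)
  )
  tibble::tibble(
    cell_id = cells,
    locus = "IGH",
    productive = TRUE,
    v_call = allele(rep(v_gene, n)),
    d_call = allele(rep(d_gene, n)),
    j_call = allele(rep(j_gene, n)),
    junction = junction,
    junction_aa = .translate_nt(junction),
    c_call = c_call,
    duplicate_count = .sample_range(
      cfg$umi_dominant_range[1], cfg$umi_dominant_range[2], n
    ),
    v_mut_count = v_mut,
    j_mut_count = j_mut,
    vj_aligned_length = vj_len,
    sequence = paste0(seq_v, junction, seq_j),
    true_clone_id = clone_id
  )
}

# Full deterministic simulation under one seed: cell roster, clone structure,
# IGH/TCR contigs, doublet collisions, and the expression matrix.
.simulate_all <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  dict <- .vdj_dictionary()

  samples <- tibble::tibble(
    sample_id = c(
      paste0("TNBC", seq_len(cfg$n_samples_tumor), recycle0 = TRUE),
      paste0("PBMC", seq_len(cfg$n_samples_blood), recycle0 = TRUE)
    ),
    compartment = c(
      rep("tumor", cfg$n_samples_tumor),
      rep("blood", cfg$n_samples_blood)
    ),
    pair = c(seq_len(cfg$n_samples_tumor), seq_len(cfg$n_samples_blood))
  )

  clusters_high <- paste0("C", seq_len(cfg$n_clusters_high))
  # tumor repertoires skew to memory/plasma clusters, blood to naive ones
  idx <- seq_len(cfg$n_clusters_high)
  w_tumor <- stats::dnorm(idx, mean = cfg$n_clusters_high * 0.55, sd = 4)
  w_blood <- stats::dnorm(idx, mean = 2, sd = 3)

  cells <- list()
  for (s in seq_len(nrow(samples))) {
    n <- cfg$n_cells_per_sample
    if (n == 0L) next
    comp <- samples$compartment[s]
    w <- if (comp == "tumor") w_tumor else w_blood
    ch <- sample(clusters_high, n, replace = TRUE, prob = w)
    cells[[s]] <- tibble::tibble(
      cell_id = sprintf("%s_BC%05d", samples$sample_id[s], seq_len(n)),
      sample_id = samples$sample_id[s],
      compartment = comp,
      pair = samples$pair[s],
      cluster_high = ch,
      cluster_low = .cluster_low_of_high(ch)
    )
  }
  roster <- dplyr::bind_rows(cells)
  n_total <- nrow(roster)

  # --- clone structure -------------------------------------------------
  roster$true_clone_id <- NA_character_
  clone_counter <- 0L
  clone_assign <- list() # clone_id -> cell ids
  clone_comp <- character(0)
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    comp <- samples$compartment[s]
    rows <- which(roster$sample_id == sid)
    frac <- if (comp == "tumor") cfg$clonal_fraction_tumor else cfg$clonal_fraction_blood
    n_clonal <- round(frac * length(rows))
    sizes <- .draw_clone_sizes(n_clonal, cfg$clone_size_distribution)
    pool <- sample(rows) # random order; clone members drawn off the top
    used <- 0L
    for (sz in sizes) {
      clone_counter <- clone_counter + 1L
      id <- sprintf("T%05d", clone_counter)
      members <- pool[(used + 1L):(used + sz)]
      used <- used + sz
      roster$true_clone_id[members] <- id
      clone_assign[[id]] <- roster$cell_id[members]
      clone_comp[id] <- comp
    }
  }
  # singletons get their own clone ids
  singleton <- which(is.na(roster$true_clone_id))
  if (length(singleton) > 0L) {
    ids <- sprintf("T%05d", clone_counter + seq_along(singleton))
    roster$true_clone_id[singleton] <- ids
    for (k in seq_along(singleton)) {
      clone_assign[[ids[k]]] <- roster$cell_id[singleton[k]]
      clone_comp[ids[k]] <- roster$compartment[singleton[k]]
    }
    clone_counter <- clone_counter + length(singleton)
  }

  # tumor clones may recruit one blood singleton from the paired sample
  multi_ids <- names(clone_assign)[lengths(clone_assign) >= 2L]
  tumor_multi <- multi_ids[clone_comp[multi_ids] == "tumor"]
  for (id in tumor_multi) {
    if (stats::runif(1) >= cfg$p_cross_compartment) next
    host_cells <- clone_assign[[id]]
    pair_idx <- roster$pair[match(host_cells[1L], roster$cell_id)]
    cand <- which(
      roster$compartment == "blood" & roster$pair == pair_idx &
        roster$true_clone_id %in% names(which(lengths(clone_assign) == 1L))
    )
    if (length(cand) == 0L) next
    pick <- cand[1L]
    old <- roster$true_clone_id[pick]
    clone_assign[[old]] <- NULL
    roster$true_clone_id[pick] <- id
    clone_assign[[id]] <- c(clone_assign[[id]], roster$cell_id[pick])
  }

  # --- IGH contigs ------------------------------------------------------
  # Each true clone gets a distinct germline key (V, D-or-absent, J,
  # junction length) drawn without replacement, so the planted partition is
  # exactly identifiable from the emitted annotations: chance key collisions
  # between unrelated cells would otherwise masquerade as clones.
  n_clones <- length(clone_assign)
  lens <- seq(30L, 75L, by = 3L)
  key_space <- length(dict$v) * (length(dict$d) + 1L) * length(dict$j) *
    length(lens)
  if (n_clones > key_space) {
    stop(
      sprintf(
        "simulation needs %d distinct germline keys but the V/D/J dictionary supports only %d; reduce the cell count.",
        n_clones, key_space
      ),
      call. = FALSE
    )
  }
  key_idx <- sample.int(key_space, n_clones) - 1L
  nd <- length(dict$d) + 1L
  key_v <- dict$v[key_idx %% length(dict$v) + 1L]
  d_slot <- (key_idx %/% length(dict$v)) %% nd
  key_d <- ifelse(d_slot == 0L, NA_character_, dict$d[pmax(d_slot, 1L)])
  key_j <- dict$j[(key_idx %/% (length(dict$v) * nd)) %% length(dict$j) + 1L]
  key_len <- lens[key_idx %/% (length(dict$v) * nd * length(dict$j)) + 1L]

  rec_list <- vector("list", n_clones)
  k <- 0L
  for (id in names(clone_assign)) {
    k <- k + 1L
    members <- clone_assign[[id]]
    comp <- clone_comp[[id]]
    if (is.null(comp) || is.na(comp)) comp <- "tumor"
    rec_list[[k]] <- .simulate_igh_for_clone(
      members, id, comp, cfg, dict,
      key = list(v = key_v[k], d = key_d[k], j = key_j[k], len = key_len[k])
    )
  }
  records <- dplyr::bind_rows(rec_list[seq_len(k)])
  records <- dplyr::left_join(
    records,
    roster[, c("cell_id", "sample_id", "compartment")],
    by = "cell_id"
  )
  ord <- match(records$cell_id, roster$cell_id)
  records <- records[order(ord), , drop = FALSE]

  truth_mut <- records[, c("cell_id", "v_mut_count", "j_mut_count")]

  # spurious second productive IGH with minor UMI support
  extra_rows <- which(stats::runif(n_total) < cfg$p_multi_productive)
  if (length(extra_rows) > 0L) {
    extras <- vector("list", length(extra_rows))
    for (i in seq_along(extra_rows)) {
      cell <- roster$cell_id[extra_rows[i]]
      comp <- roster$compartment[extra_rows[i]]
      ex <- .simulate_igh_for_clone(cell, NA_character_, comp, cfg, dict)
      ex$duplicate_count <- .sample_range(
        cfg$umi_minor_range[1], cfg$umi_minor_range[2], 1L
      )
      ex$sample_id <- roster$sample_id[extra_rows[i]]
      ex$compartment <- comp
      extras[[i]] <- ex
    }
    records <- dplyr::bind_rows(records, dplyr::bind_rows(extras))
  }

  # occasional non-productive IGH contig (ignored by productive selection)
  np_rows <- which(stats::runif(n_total) < 0.05)
  if (length(np_rows) > 0L) {
    nps <- vector("list", length(np_rows))
    for (i in seq_along(np_rows)) {
      cell <- roster$cell_id[np_rows[i]]
      comp <- roster$compartment[np_rows[i]]
      np <- .simulate_igh_for_clone(cell, NA_character_, comp, cfg, dict)
      np$productive <- FALSE
      np$duplicate_count <- .sample_range(
        cfg$umi_minor_range[1], cfg$umi_minor_range[2], 1L
      )
      np$sample_id <- roster$sample_id[np_rows[i]]
      np$compartment <- comp
      nps[[i]] <- np
    }
    records <- dplyr::bind_rows(records, dplyr::bind_rows(nps))
  }

  # TCR contamination: both TRA and TRB assembled on a B-cell barcode
  tcr_rows <- which(stats::runif(n_total) < cfg$p_tcr)
  if (length(tcr_rows) > 0L) {
    tcr <- tibble::tibble(
      cell_id = rep(roster$cell_id[tcr_rows], each = 2L),
      locus = rep(c("TRA", "TRB"), length(tcr_rows)),
      productive = TRUE,
      v_call = paste0("TRV", sample(1:10, 2L * length(tcr_rows), replace = TRUE)),
      d_call = NA_character_,
      j_call = paste0("TRJ", sample(1:10, 2L * length(tcr_rows), replace = TRUE)),
      junction = .random_dna(2L * length(tcr_rows), 36L),
      junction_aa = NA_character_,
      c_call = NA_character_,
      duplicate_count = sample(2:20, 2L * length(tcr_rows), replace = TRUE),
      v_mut_count = 0L,
      j_mut_count = 0L,
      vj_aligned_length = 300L,
      sequence = .random_dna(2L * length(tcr_rows), 60L),
      true_clone_id = NA_character_,
      sample_id = rep(roster$sample_id[tcr_rows], each = 2L),
      compartment = rep(roster$compartment[tcr_rows], each = 2L)
    )
    tcr$junction_aa <- .translate_nt(tcr$junction)
    records <- dplyr::bind_rows(records, tcr)
  }

  # --- doublets: barcode collisions ------------------------------------
  n_doublets <- floor(cfg$p_doublet * n_total)
  doublet_hosts <- character(0)
  dropped_donors <- character(0)
  if (n_doublets >= 1L && n_total >= 2L * n_doublets) {
    picked <- sample(roster$cell_id, 2L * n_doublets)
    doublet_hosts <- picked[seq_len(n_doublets)]
    dropped_donors <- picked[n_doublets + seq_len(n_doublets)]
    remap <- stats::setNames(doublet_hosts, dropped_donors)
    hit <- records$cell_id %in% dropped_donors
    records$cell_id[hit] <- remap[records$cell_id[hit]]
    host_meta <- roster[match(doublet_hosts, roster$cell_id), ]
    records$sample_id[hit] <- host_meta$sample_id[
      match(records$cell_id[hit], doublet_hosts)
    ]
    records$compartment[hit] <- host_meta$compartment[
      match(records$cell_id[hit], doublet_hosts)
    ]
  }

  keep <- !(roster$cell_id %in% dropped_donors)
  roster_out <- roster[keep, , drop = FALSE]

  # --- cell-level QC covariates and true phase --------------------------
  n_out <- nrow(roster_out)
  phase <- sample(c("S", "G2M", "other"), n_out,
    replace = TRUE, prob = c(0.10, 0.05, 0.85)
  )
  total_umi <- pmax(round(stats::rlnorm(n_out, log(3000), 0.35)), cfg$min_total_umi)
  n_genes_cell <- pmin(round(total_umi * stats::runif(n_out, 0.30, 0.55)), 4800L)
  mito <- stats::rbeta(n_out, 2, 28)
  # planted QC failures
  fail_low <- stats::runif(n_out) < 0.02
  fail_high <- !fail_low & stats::runif(n_out) < 0.01
  fail_mito <- !fail_low & !fail_high & stats::runif(n_out) < 0.02
  n_genes_cell[fail_low] <- sample(50:199, sum(fail_low), replace = TRUE)
  n_genes_cell[fail_high] <- sample(5001:7000, sum(fail_high), replace = TRUE)
  mito[fail_mito] <- stats::runif(sum(fail_mito), 0.51, 0.9)

  meta <- tibble::tibble(
    cell_id = roster_out$cell_id,
    sample_id = roster_out$sample_id,
    compartment = roster_out$compartment,
    cluster_low = roster_out$cluster_low,
    cluster_high = roster_out$cluster_high,
    total_umi = as.integer(total_umi),
    n_genes = as.integer(n_genes_cell),
    mito_fraction = mito
  )

  # --- expression matrix ------------------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  gene_sets <- list(
    signature = gene_ids[1:10],
    s_phase = gene_ids[11:30],
    g2m_phase = gene_ids[31:50]
  )
  sig_cluster <- "C3"
  base_mu <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  lib <- pmax(
    round(stats::rlnorm(n_out, log(3000), 0.35)),
    cfg$min_total_umi
  )
  mu <- matrix(base_mu, nrow = cfg$n_genes, ncol = n_out)
  in_sig_cluster <- roster_out$cluster_high == sig_cluster
  sig_idx <- match(gene_sets$signature, gene_ids)
  mu[sig_idx, in_sig_cluster] <- mu[sig_idx, in_sig_cluster] * exp(cfg$sig_effect)
  s_idx <- match(gene_sets$s_phase, gene_ids)
  g2m_idx <- match(gene_sets$g2m_phase, gene_ids)
  mu[s_idx, phase == "S"] <- mu[s_idx, phase == "S"] * cfg$cc_effect
  mu[g2m_idx, phase == "G2M"] <- mu[g2m_idx, phase == "G2M"] * cfg$cc_effect
  mu <- sweep(mu, 2L, colSums(mu), "/")
  mu <- sweep(mu, 2L, lib, "*")
  counts <- matrix(
    stats::rpois(cfg$n_genes * n_out, as.vector(mu)),
    nrow = cfg$n_genes
  )
  # enforce the configured per-cell floor deterministically
  deficit <- pmax(cfg$min_total_umi - colSums(counts), 0L)
  if (any(deficit > 0L)) {
    counts[1L, ] <- counts[1L, ] + deficit
  }
  dimnames(counts) <- list(gene_ids, roster_out$cell_id)
  counts <- Matrix::Matrix(counts, sparse = TRUE)

  truth_mut <- truth_mut[truth_mut$cell_id %in% roster_out$cell_id, ]
  truth_mut <- truth_mut[!duplicated(truth_mut$cell_id), ]
  truth <- tibble::tibble(
    cell_id = roster_out$cell_id,
    true_clone_id = roster_out$true_clone_id,
    true_phase = phase,
    is_doublet = roster_out$cell_id %in% doublet_hosts
  )
  truth <- dplyr::left_join(truth, truth_mut, by = "cell_id")
  names(truth)[names(truth) == "v_mut_count"] <- "true_v_mut_count"
  names(truth)[names(truth) == "j_mut_count"] <- "true_j_mut_count"

  list(
    records = tibble::as_tibble(records),
    meta = meta,
    ground_truth = list(
      cells = truth,
      doublet_barcodes = doublet_hosts,
      signature_cluster = sig_cluster
    ),
    counts = counts,
    gene_sets = gene_sets,
    config = cfg
  )
}

#' Simulate a paired single-cell BCR repertoire
#'
#' Generates AIRR-style IGH rearrangement records for multi-sample tumor and
#' blood repertoires with planted clones (shared V/D/J genes and junction
#' length), compartment-specific somatic hypermutation rates and isotype
#' switching probabilities, spurious multi-productive contigs, TCR
#' contamination, and doublet barcode collisions.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `records` (tibble, one row per contig, AIRR
#'   column names plus `v_mut_count`, `j_mut_count`, `vj_aligned_length`,
#'   `sequence`), `meta` (per-cell metadata tibble), and `ground_truth`
#'   (list with per-cell truth tibble, doublet barcodes, and the cluster
#'   carrying the planted signature shift).
#' @examples
#' sim <- simulate_repertoire(sim_config(n_cells_per_sample = 50, seed = 7))
#' dplyr::count(sim$records, locus)
#' @export
simulate_repertoire <- function(config) {
  out <- .simulate_all(config)
  list(records = out$records, meta = out$meta, ground_truth = out$ground_truth)
}

#' Simulate a gene-by-cell UMI count matrix with planted structure
#'
#' Produces a sparse non-negative integer matrix whose barcodes match
#' [simulate_repertoire()] under the same configuration. A designated
#' signature gene set is shifted upward in one cluster and designated
#' S-phase / G2M gene sets are boosted in cycling cells.
#'
#' @param config a [sim_config()] object.
#' @return A list with `counts` (dgCMatrix genes x cells), `meta` (per-cell
#'   metadata), `gene_sets` (the planted signature / S / G2M gene id sets),
#'   and `ground_truth`.
#' @examples
#' sim <- simulate_expression(sim_config(n_cells_per_sample = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_expression <- function(config) {
  out <- .simulate_all(config)
  list(
    counts = out$counts, meta = out$meta, gene_sets = out$gene_sets,
    ground_truth = out$ground_truth
  )
}

#' Simulate an external reference clonotype set with planted overlap
#'
#' Emulates a large external blood-donor clonotype table (the kind public
#' clones are matched against) as a synthetic stand-in: `n_reference`
#' clonotypes with V/J genes from the synthetic dictionary and random CDRH3
#' amino-acid sequences, of which a planted fraction of the study's
#' clonotypes is included verbatim. The overlap fraction is the condition
#' the public-clone machinery is exercised under; `0.025` emulates the
#' few-percent public-clone rates typical of blood repertoires.
#'
#' @param study_clonotypes tibble (`v_gene`, `j_gene`, `cdr3_aa`), e.g. from
#'   [extract_clonotypes()].
#' @param n_reference number of reference clonotypes to generate.
#' @param overlap_fraction fraction of unique study clonotypes planted into
#'   the reference.
#' @param seed random seed.
#' @return A deduplicated clonotype tibble.
#' @export
simulate_reference_clonotypes <- function(study_clonotypes,
                                          n_reference = 10000,
                                          overlap_fraction = 0.025,
                                          seed = 1L) {
  study <- dplyr::distinct(tibble::as_tibble(study_clonotypes))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("`overlap_fraction` must be in [0, 1].", call. = FALSE)
  }
  dict <- .vdj_dictionary()
  withr::with_seed(seed, {
    n_planted <- round(overlap_fraction * nrow(study))
    planted <- study[sample.int(nrow(study), n_planted), , drop = FALSE]
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    len <- .sample_range(10L, 25L, n_reference)
    novel <- tibble::tibble(
      v_gene = sample(dict$v, n_reference, replace = TRUE),
      j_gene = sample(dict$j, n_reference, replace = TRUE),
      cdr3_aa = vapply(
        len,
        function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
        character(1)
      )
    )
    dplyr::distinct(dplyr::bind_rows(planted, novel))
  })
}

#' Simulate paired repertoire and expression data in one pass
#'
#' @param config a [sim_config()] object.
#' @return A list with `records`, `meta`, `counts`, `gene_sets`,
#'   `ground_truth`, and the `config` used.
#' @examples
#' sim <- simulate_paired(sim_config(n_cells_per_sample = 50, seed = 7))
#' names(sim)
#' @export
simulate_paired <- function(config) {
  .simulate_all(config)
}
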