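# Independent oracles and small fixture builders shared across tests.

# Brute-force clone partition: all-pairs field comparison with union-find.
# Deliberately avoids the package's key construction.
oracle_clone_partition <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  gene <- function(x) sub("\\*.*$", "", x)
  d <- df$d_call
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      same_d <- (is.na(d[i]) && is.na(d[j])) ||
        (!is.na(d[i]) && !is.na(d[j]) && gene(d[i]) == gene(d[j]))
      if (same_d &&
        gene(df$v_call[i]) == gene(df$v_call[j]) &&
        gene(df$j_call[i]) == gene(df$j_call[j]) &&
        nchar(df$junction[i]) == nchar(df$junction[j])) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonicalize a partition labeling so two labelings can be compared up to
# renaming: label each element by the first index of its block.
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# Brute-force sharing-event enumeration over explicit cell pairs.
oracle_sharing_counts <- function(records, meta, cluster_col, key_col) {
  cl <- meta[[cluster_col]][match(records$cell_id, meta$cell_id)]
  comp <- records$compartment
  key <- records[[key_col]]
  n <- nrow(records)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      if (is.na(key[i]) || is.na(key[j]) || key[i] != key[j]) next
      grp <- if (comp[i] == "tumor" && comp[j] == "tumor") {
        "TNBC"
      } else if (comp[i] == "blood" && comp[j] == "blood") {
        "PBMC"
      } else {
        "mixed"
      }
      if (grp == "mixed") {
        a <- if (comp[i] == "tumor") cl[i] else cl[j]
        b <- if (comp[i] == "tumor") cl[j] else cl[i]
      } else {
        a <- min(cl[i], cl[j])
        b <- max(cl[i], cl[j])
      }
      k <- paste(grp, a, b, sep = "|")
      out[[k]] <- (out[[k]] %||% 0L) + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-written 12-cell contig fixture exercising every QC boundary: clean
# singles, 55/5 and 50/5 multi-productive cells, a none-productive cell,
# IGH+TRA-only, IGH+TRA+TRB, and T cells without IGH.
qc_boundary_fixture <- function() {
  row <- function(cell, locus, productive, umi, seq) {
    tibble::tibble(
      cell_id = cell, locus = locus, productive = productive,
      v_call = "IGHV1*01", d_call = "IGHD1*01", j_call = "IGHJ1*01",
      junction = "TGTGCGAGAGGG", junction_aa = "CARG", c_call = "IGHM",
      duplicate_count = as.integer(umi), v_mut_count = 0L, j_mut_count = 0L,
      vj_aligned_length = 300L, sequence = seq
    )
  }
  dplyr::bind_rows(
    row("cell01", "IGH", TRUE, 30, "AAA"), # clean single productive
    row("cell02", "IGH", TRUE, 55, "CCC"), # dominant passes 10-fold
    row("cell02", "IGH", TRUE, 5, "GGG"),
    row("cell03", "IGH", TRUE, 50, "TTT"), # exactly 10-fold: rejected
    row("cell03", "IGH", TRUE, 5, "ACA"),
    row("cell04", "IGH", FALSE, 40, "AGA"), # only non-productive IGH
    row("cell05", "IGH", TRUE, 20, "ATA"), # IGH + TRA only: retained
    row("cell05", "TRA", TRUE, 10, "TTA"),
    row("cell06", "IGH", TRUE, 20, "CGC"), # IGH + TRA + TRB: flagged
    row("cell06", "TRA", TRUE, 8, "CTC"),
    row("cell06", "TRB", TRUE, 9, "GAG"),
    row("cell07", "TRA", TRUE, 12, "GCG"), # T cell, both chains, no IGH
    row("cell07", "TRB", TRUE, 11, "TAT"),
    row("cell08", "IGH", TRUE, 3, "TGT"), # low-UMI single productive
    row("cell09", "IGH", TRUE, 10, "AAC"), # three productive contigs
    row("cell09", "IGH", TRUE, 60, "AAG"),
    row("cell09", "IGH", TRUE, 5, "AAT"),
    row("cell10", "TRA", TRUE, 7, "CCA"), # TRA only, no IGH
    row("cell11", "IGH", TRUE, 61, "CCG"), # 61 > 10*6: strict pass... no, 61>60
    row("cell11", "IGH", TRUE, 6, "CCT"),
    row("cell12", "IGH", TRUE, 60, "GGA"), # 60 = 10*6: rejected
    row("cell12", "IGH", TRUE, 6, "GGC")
  )
}

# Tiny deterministic expression matrix with named genes/cells.
toy_counts <- function(values, n_genes, n_cells) {
  m <- matrix(values, nrow = n_genes, ncol = n_cells)
  dimnames(m) <- list(
    sprintf("G%03d", seq_len(n_genes)),
    sprintf("cell%02d", seq_len(n_cells))
  )
  Matrix::Matrix(m, sparse = TRUE)
}
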