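# Fixture: hand-placed cells with known clone/sequence structure.
sharing_fixture <- function() {
  rec <- tibble::tibble(
    cell_id = paste0("c", 1:9),
    compartment = c(rep("tumor", 5), rep("blood", 4)),
    clone_id = c("K1", "K1", "K1", "K2", "K3", "K2", "K4", "K4", "K5"),
    sequence = c("s1", "s1", "s2", "s3", "s4", "s5", "s6", "s6", "s7")
  )
  meta <- tibble::tibble(
    cell_id = rec$cell_id,
    compartment = rec$compartment,
    cluster_low = c("A", "A", "A", "B", "B", "A", "B", "B", "A"),
    cluster_high = paste0("H", c(1, 1, 2, 3, 3, 1, 2, 2, 1))
  )
  list(records = rec, meta = meta)
}

test_that("a 3-cell single-cluster tumor clone yields 3 diagonal events", {
  fx <- sharing_fixture()
  ev <- count_sharing_events(fx$records, fx$meta, "same_germline", "low")
  tnbc_aa <- ev$n_events[ev$group == "TNBC" & ev$cluster_a == "A" &
    ev$cluster_b == "A"]
  expect_equal(tnbc_aa, 3L) # choose(3, 2)
})

test_that("a tumor-blood clone pair lands only in the mixed matrix", {
  fx <- sharing_fixture()
  ev <- count_sharing_events(fx$records, fx$meta, "same_germline", "low")
  # K2 spans c4 (tumor, B) and c6 (blood, A): mixed, tumor side first
  mixed <- ev[ev$group == "mixed" & ev$n_events > 0, ]
  expect_equal(nrow(mixed), 1)
  expect_equal(mixed$cluster_a, "B") # tumor-side cluster
  expect_equal(mixed$cluster_b, "A") # blood-side cluster
  expect_equal(mixed$n_events, 1L)
  expect_equal(sum(ev$n_events[ev$group == "TNBC"]), 3L) # only K1
  expect_equal(sum(ev$n_events[ev$group == "PBMC"]), 1L) # only K4
})

test_that("no shared lineage means all-zero matrices", {
  fx <- sharing_fixture()
  rec <- dplyr::mutate(fx$records, clone_id = paste0("solo", dplyr::row_number()))
  ev <- count_sharing_events(rec, fx$meta, "same_germline", "low")
  expect_true(all(ev$n_events == 0L))
  nm <- normalize_sharing(ev)
  expect_true(all(nm$n_normalized == 0, na.rm = TRUE))
})

test_that("same-sequence events key on the full observed IGH sequence", {
  fx <- sharing_fixture()
  ev <- count_sharing_events(fx$records, fx$meta, "same_sequence", "low")
  # s1 pair (c1, c2, tumor cluster A) and s6 pair (c7, c8, blood cluster B)
  expect_equal(sum(ev$n_events), 2L)
  expect_equal(
    ev$n_events[ev$group == "TNBC" & ev$cluster_a == "A" & ev$cluster_b == "A"],
    1L
  )
  expect_equal(
    ev$n_events[ev$group == "PBMC" & ev$cluster_a == "B" & ev$cluster_b == "B"],
    1L
  )
})

test_that("event counting matches brute-force pair enumeration on simulation", {
  sim <- simulate_repertoire(sim_config(
    n_cells_per_sample = 120, n_samples_tumor = 2, n_samples_blood = 2,
    p_doublet = 0, p_multi_productive = 0, p_tcr = 0,
    p_cross_compartment = 0.3, seed = 8
  ))
  rec <- assign_clones(
    sim$records[sim$records$locus == "IGH" & sim$records$productive, ]
  )
  for (mode_key in list(c("same_germline", "clone_id"),
                        c("same_sequence", "sequence"))) {
    ev <- count_sharing_events(rec, sim$meta, mode_key[1], "high")
    oracle <- oracle_sharing_counts(rec, sim$meta, "cluster_high", mode_key[2])
    got <- ev[ev$n_events > 0, ]
    expect_equal(nrow(got), length(oracle))
    for (i in seq_len(nrow(got))) {
      k <- paste(got$group[i], got$cluster_a[i], got$cluster_b[i], sep = "|")
      expect_equal(got$n_events[i], oracle[[k]])
    }
    # conservation: total events = sum over key groups of choose(size, 2)
    sizes <- table(rec[[mode_key[2]]])
    expect_equal(sum(ev$n_events), sum(choose(sizes, 2)))
    # partition: TNBC + PBMC + mixed = all qualifying pairs
    expect_equal(
      sum(ev$n_events[ev$group == "TNBC"]) +
        sum(ev$n_events[ev$group == "PBMC"]) +
        sum(ev$n_events[ev$group == "mixed"]),
      sum(choose(sizes, 2))
    )
  }
})

test_that("within-compartment matrices are symmetric", {
  sim <- simulate_repertoire(sim_config(
    n_cells_per_sample = 150, p_cross_compartment = 0.2, seed = 12
  ))
  qc <- repertoire_qc(sim$records, sim$meta)
  rec <- assign_clones(qc$records)
  ev <- normalize_sharing(
    count_sharing_events(rec, qc$meta, "same_germline", "high")
  )
  for (grp in c("TNBC", "PBMC")) {
    m_raw <- sharing_matrix(ev, grp, "n_events")
    m_norm <- sharing_matrix(ev, grp, "n_normalized")
    expect_identical(m_raw, t(m_raw))
    expect_identical(m_norm, t(m_norm))
  }
})

test_that("normalization implements the per-10,000 formula", {
  ev <- tibble::tibble(
    mode = "same_germline", group = "TNBC",
    cluster_a = c("A", "B", "C", "D"),
    cluster_b = c("B", "B", "C", "D"),
    n_events = c(4L, 5L, 0L, 0L),
    n_a = c(40L, 100L, 30L, 0L),
    n_b = c(20L, 100L, 30L, 0L)
  )
  nm <- normalize_sharing(ev)
  expect_equal(nm$n_normalized[1], 200) # (4/40)*(4/20)*1e4
  expect_equal(nm$n_normalized[2], 25) # (5/100)^2*1e4
  expect_equal(nm$n_normalized[3], 0) # zero events -> zero
  expect_true(is.na(nm$n_normalized[4])) # empty cluster -> masked

  # zero-size cluster with events is inconsistent data
  bad <- dplyr::mutate(ev, n_a = c(0L, 100L, 30L, 0L))
  expect_error(normalize_sharing(bad), "zero-size")

  # random inputs against an independent evaluation
  set.seed(9)
  rnd <- tibble::tibble(
    mode = "same_germline", group = "TNBC",
    cluster_a = "X", cluster_b = "Y",
    n_events = rpois(1000, 5),
    n_a = sample(1:500, 1000, replace = TRUE),
    n_b = sample(1:500, 1000, replace = TRUE)
  )
  got <- normalize_sharing(rnd)$n_normalized
  want <- (rnd$n_events / rnd$n_a) * (rnd$n_events / rnd$n_b) * 10000
  expect_equal(got, want, tolerance = 1e-15)
})

test_that("normalized sharing is monotone in events and sizes", {
  base <- tibble::tibble(
    mode = "m", group = "TNBC", cluster_a = "A", cluster_b = "B",
    n_events = 5L, n_a = 50L, n_b = 80L
  )
  v0 <- normalize_sharing(base)$n_normalized
  more_events <- normalize_sharing(dplyr::mutate(base, n_events = 6L))$n_normalized
  bigger_a <- normalize_sharing(dplyr::mutate(base, n_a = 60L))$n_normalized
  bigger_b <- normalize_sharing(dplyr::mutate(base, n_b = 90L))$n_normalized
  expect_gt(more_events, v0)
  expect_lt(bigger_a, v0)
  expect_lt(bigger_b, v0)
})

test_that("unlabeled cells are reported by barcode", {
  fx <- sharing_fixture()
  meta <- fx$meta[-3, ]
  expect_error(
    count_sharing_events(fx$records, meta, "same_germline", "low"),
    "c3"
  )
})
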