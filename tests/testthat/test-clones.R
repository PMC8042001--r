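test_that("clone identity keys on V/D/J genes and junction length only", {
  x <- tibble::tibble(
    cell_id = c("a", "b", "c", "d", "e"),
    v_call = c("IGHV1*01", "IGHV1*02", "IGHV1*01", "IGHV1*01", "IGHV1*01"),
    d_call = c("IGHD2*01", "IGHD2*01", "IGHD2*01", NA, NA),
    j_call = c("IGHJ4*01", "IGHJ4*01", "IGHJ5*01", "IGHJ4*01", "IGHJ4*01"),
    junction = c("TGTGCGAGA", "TGTAAAAGA", "TGTGCGAGA", "TGTGCGAGA", "TGTGCGAGA")
  )
  res <- assign_clones(x)
  # same V/D/J and junction length, different junction sequence: same clone
  expect_equal(res$clone_id[1], res$clone_id[2])
  # different J gene: different clone
  expect_false(res$clone_id[3] == res$clone_id[1])
  # absent D merges only with absent D
  expect_false(res$clone_id[4] == res$clone_id[1])
  expect_equal(res$clone_id[4], res$clone_id[5])

  expect_error(assign_clones(dplyr::bind_rows(x, x[1, ])), "duplicate cell_id")
})

test_that("clone assignment equals the brute-force all-pairs oracle", {
  for (seed in c(3, 17)) {
    sim <- simulate_repertoire(sim_config(
      n_cells_per_sample = 100, n_samples_tumor = 1, n_samples_blood = 1,
      p_doublet = 0, p_multi_productive = 0, p_tcr = 0, seed = seed
    ))
    rec <- sim$records[sim$records$locus == "IGH" & sim$records$productive, ]
    res <- assign_clones(rec)
    oracle <- oracle_clone_partition(rec)
    expect_identical(
      canonical_partition(res$clone_id),
      canonical_partition(oracle)
    )
    # conservation: clone sizes sum to cell count
    ct <- clone_table(res)
    expect_equal(sum(ct$size), nrow(rec))
  }
})

test_that("SHM statistics follow the V+J definition", {
  rec <- tibble::tibble(
    v_mut_count = c(0L, 5L), j_mut_count = c(0L, 1L),
    vj_aligned_length = c(300L, 300L)
  )
  res <- add_shm_stats(rec)
  expect_equal(res$mut_count, c(0L, 6L))
  expect_equal(res$mut_frequency, c(0, 0.02))
  expect_true(all(res$mut_frequency >= 0 & res$mut_frequency <= 1))
  # adding a mutation at fixed length cannot decrease the frequency
  more <- add_shm_stats(dplyr::mutate(rec, v_mut_count = v_mut_count + 1L))
  expect_true(all(more$mut_frequency >= res$mut_frequency))

  expect_error(
    add_shm_stats(tibble::tibble(
      v_mut_count = 1L, j_mut_count = 0L, vj_aligned_length = 0L
    )),
    "positive"
  )
})

test_that("isotype class, switch and germline status are definitional", {
  rec <- tibble::tibble(
    c_call = c("IGHG2", "IGHM", "IGHD", "IGHA1", NA),
    v_mut_count = c(3L, 0L, 4L, 0L, 2L),
    j_mut_count = c(0L, 0L, 0L, 0L, 0L)
  )
  res <- add_bcr_status(rec)
  expect_equal(res$isotype_class, c("IGG", "IGM", "IGD", "IGA", "unknown"))
  expect_equal(res$switched, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$germline, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # the non-germline non-switched category (mutated IGM/IGD) is identifiable
  expect_true(!res$germline[3] && !res$switched[3])
  expect_false(res$isotype_known[5])
})

test_that("repertoire summary computes clonal fraction over cells", {
  # 100 cells: one clone of 19 + 81 singletons -> clonal fraction 19%
  n <- 100
  rec <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:n),
    v_call = c(rep("IGHV1", 19), paste0("IGHV", 100 + 1:81)),
    d_call = "IGHD1",
    j_call = "IGHJ1",
    junction = strrep("A", 30),
    v_mut_count = 0L, j_mut_count = 0L, vj_aligned_length = 300L,
    c_call = "IGHM",
    compartment = "tumor"
  )
  res <- repertoire_summary(assign_clones(rec))
  expect_equal(res$clonal_fraction, 0.19)
  expect_equal(res$germline_fraction, 1)
  expect_equal(res$frac_IGM, 1)

  # all-singleton repertoire has clonal fraction 0
  singles <- dplyr::mutate(rec, v_call = paste0("IGHV", 1:n))
  expect_equal(repertoire_summary(assign_clones(singles))$clonal_fraction, 0)

  # germline + non-germline fractions always partition each group
  sim <- simulate_repertoire(sim_config(n_cells_per_sample = 150, seed = 4))
  qc <- repertoire_qc(sim$records, sim$meta)
  s <- repertoire_summary(assign_clones(qc$records))
  expect_true(all(s$germline_fraction >= 0 & s$germline_fraction <= 1))
  iso_cols <- grep("^frac_", names(s), value = TRUE)
  expect_equal(unname(rowSums(s[, iso_cols])), rep(1, nrow(s)))
})

test_that("per-clone mean mutation frequency averages member frequencies", {
  rec <- tibble::tibble(
    cell_id = c("a", "b"),
    v_call = "IGHV1", d_call = "IGHD1", j_call = "IGHJ1",
    junction = strrep("A", 30),
    v_mut_count = c(3L, 9L), j_mut_count = 0L, vj_aligned_length = 300L
  )
  ct <- clone_table(assign_clones(rec))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$mean_mut_frequency, mean(c(0.01, 0.03)))
})

test_that("public clone matching counts unique shared clonotypes", {
  mk <- function(v, j, aa) tibble::tibble(v_gene = v, j_gene = j, cdr3_aa = aa)
  study <- mk(
    paste0("IGHV", 1:40), paste0("IGHJ", rep(1:4, 10)),
    paste0("CAR", LETTERS[(0:39) %% 26 + 1], "W")
  )
  # disjoint reference: zero shared
  ref0 <- mk("IGHV99", "IGHJ9", "CARZZZW")
  r0 <- public_clone_fraction(study, ref0)
  expect_equal(r0$shared_count, 0)
  expect_equal(r0$percentage, 0)
  # identical reference: 100%
  r1 <- public_clone_fraction(study, study)
  expect_equal(r1$shared_count, 40)
  expect_equal(r1$percentage, 100)
  # 4 of 40 shared: 10%; duplicates in either set must not inflate counts
  ref4 <- dplyr::bind_rows(study[1:4, ], study[1:4, ], ref0)
  r4 <- public_clone_fraction(dplyr::bind_rows(study, study[1:10, ]), ref4)
  expect_equal(r4$shared_count, 4)
  expect_equal(r4$n_study, 40)
  expect_equal(r4$percentage, 10)

  expect_error(public_clone_fraction(study[0, ], ref0), "undefined")
})

test_that("the 2x2 public-clone test matches the Pearson statistic", {
  mk <- function(n, tag) {
    tibble::tibble(
      v_gene = paste0("IGHV", seq_len(n)), j_gene = "IGHJ1",
      cdr3_aa = paste0("CAR", tag, seq_len(n))
    )
  }
  study <- mk(50, "S")
  other <- mk(80, "O")
  reference <- dplyr::bind_rows(study[1:10, ], other[1:12, ])
  res <- public_clone_fraction(study, reference, other = other)
  tab <- res$table
  expect_equal(unname(tab[, "study"]), c(10, 40))
  expect_equal(unname(tab[, "other"]), c(12, 68))
  # independent Pearson chi-square, no continuity correction
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  expect_equal(unname(res$htest$statistic), x2, tolerance = 1e-12)

  g <- glance(res)
  expect_equal(g$percentage, 20)
  expect_equal(g$statistic, x2, tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_equal(td$percentage[td$cohort == "other"], 15)
})
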