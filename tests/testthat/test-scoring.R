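test_that("signature z-scores are centered and scaled; constants give zeros", {
  set.seed(2)
  counts <- toy_counts(rpois(50 * 40, 5) + 1, 50, 40)
  expr <- normalize_library(counts)
  sc <- score_signature(expr, rownames(counts)[1:8])
  expect_equal(mean(sc$zscore), 0, tolerance = 1e-8)
  expect_equal(sd(sc$zscore), 1, tolerance = 1e-8)

  # constant matrix: all z-scores exactly 0, never NaN
  const <- toy_counts(rep(3, 20 * 10), 20, 10)
  scc <- score_signature(normalize_library(const), rownames(const)[1:5])
  expect_equal(scc$zscore, rep(0, 10))

  # cluster means weighted by cluster size recombine to the global mean 0
  meta <- tibble::tibble(
    cell_id = colnames(counts),
    cluster_high = rep(c("C1", "C2", "C3", "C4"), each = 10)
  )
  cm <- cluster_signature_means(sc, meta)
  expect_equal(sum(cm$mean_zscore * cm$n_cells), 0, tolerance = 1e-8)

  # absent genes are dropped with a warning; all-absent is an error
  expect_warning(
    score_signature(expr, c(rownames(counts)[1], "NOT_A_GENE")),
    "absent"
  )
  expect_error(score_signature(expr, c("NOPE1", "NOPE2")), "none of the")
})

test_that("a planted cluster shift surfaces as the top cluster mean z-score", {
  cfg <- sim_config(
    n_cells_per_sample = 400, n_samples_tumor = 1, n_samples_blood = 1,
    sig_effect = 1.5, seed = 6
  )
  expr <- simulate_expression(cfg)
  sc <- score_signature(normalize_library(expr$counts), expr$gene_sets$signature)
  cm <- cluster_signature_means(sc, expr$meta)
  top <- cm$cluster[which.max(cm$mean_zscore)]
  expect_equal(top, expr$ground_truth$signature_cluster)
})

test_that("cycle score is the UMI fraction in cell-cycle genes", {
  counts <- toy_counts(0, 10, 3)
  counts["G001", ] <- c(30, 0, 600)
  counts["G002", ] <- c(570, 10, 0)
  cc <- cell_cycle_score(counts, "G001")
  expect_equal(cc$cycle_score, c(30 / 600, 0, 1))

  # conservation: UMI-weighted mean of per-cell scores equals the pooled ratio
  set.seed(3)
  big <- toy_counts(rpois(60 * 30, 4) + 1, 60, 30)
  genes <- rownames(big)[5:14]
  sc <- cell_cycle_score(big, genes)
  totals <- Matrix::colSums(big)
  pooled <- sum(big[genes, ]) / sum(totals)
  expect_equal(sum(sc$cycle_score * totals) / sum(totals), pooled,
    tolerance = 1e-12
  )

  zero <- toy_counts(0, 5, 2)
  expect_error(cell_cycle_score(zero, "G001"), "cell01")
})

test_that("phase assignment matches the strict threshold truth table", {
  grid <- expand.grid(
    s = c(-0.2, 0, 0.05, 0.1, 0.100001, 0.2, 0.3),
    g2m = c(-0.2, 0, 0.05, 0.1, 0.100001, 0.2, 0.3)
  )
  got <- assign_phase(grid$s, grid$g2m)
  # exhaustive oracle, written straight from the rule
  want <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]
    g <- grid$g2m[i]
    want[i] <- if (s > 0.1 && s > g) "S" else if (g > 0.1 && g > s) "G2M" else "other"
  }
  expect_identical(got, want)

  # quoted examples: (0.2, 0.05) -> S; (0.09, 0.09) -> other; tie -> other
  expect_identical(
    assign_phase(c(0.2, 0.09, 0.3), c(0.05, 0.09, 0.3)),
    c("S", "other", "other")
  )
  expect_error(assign_phase(c(0.1, NA), c(0, 0)), "finite")
})

test_that("cell-cycle pipeline recovers planted cycling cells above chance", {
  cfg <- sim_config(
    n_cells_per_sample = 300, n_samples_tumor = 1, n_samples_blood = 1,
    seed = 14
  )
  expr <- simulate_expression(cfg)
  res <- score_cell_cycle(
    expr$counts, expr$gene_sets$s_phase, expr$gene_sets$g2m_phase
  )
  truth <- expr$ground_truth$cells
  joined <- dplyr::inner_join(res, truth, by = "cell_id")
  # cycling cells carry a boosted share of cell-cycle UMIs
  expect_gt(
    mean(joined$cycle_score[joined$true_phase != "other"]),
    mean(joined$cycle_score[joined$true_phase == "other"])
  )
  # planted S cells score higher on S than G2M modules on average
  s_cells <- joined[joined$true_phase == "S", ]
  expect_gt(mean(s_cells$s_score - s_cells$g2m_score), 0)
})

test_that("tertile stratification uses floor(n * fraction) per tail", {
  mk <- function(n) {
    tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)), score = rnorm(n))
  }
  set.seed(10)
  df279 <- stratify_patients(mk(279))
  expect_equal(sum(df279$group == "top"), 92)
  expect_equal(sum(df279$group == "bottom"), 92)

  df100 <- stratify_patients(mk(100))
  expect_equal(sum(df100$group == "top"), 33)
  expect_equal(sum(df100$group == "bottom"), 33)

  # score separation: every top score >= every bottom score
  expect_gte(
    min(df279$score[df279$group == "top"]),
    max(df279$score[df279$group == "bottom"])
  )

  # degenerate all-tied scores: groups still size k, disjoint, by patient_id
  tied <- tibble::tibble(patient_id = sprintf("P%03d", 1:10), score = 1)
  st <- stratify_patients(tied)
  expect_equal(sum(st$group == "top"), 3)
  expect_equal(sum(st$group == "bottom"), 3)
  expect_equal(st$patient_id[st$group == "bottom"], c("P001", "P002", "P003"))
  expect_equal(st$patient_id[st$group == "top"], c("P008", "P009", "P010"))

  expect_error(stratify_patients(mk(100), fraction = 0.6), "0.5")
  expect_error(stratify_patients(mk(100), fraction = 0), "0.5")
  expect_error(stratify_patients(mk(2)), "at least 3")
})

test_that("stratified groups plug into standard survival tooling", {
  set.seed(15)
  df <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:120),
    score = rnorm(120),
    time = rexp(120, 0.02),
    event = rbinom(120, 1, 0.6)
  )
  st <- stratify_patients(df)
  grp <- st[st$group != "middle", ]
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = grp)
  expect_s3_class(fit, "survdiff")
  expect_equal(sum(fit$n), 2 * floor(120 * 0.33))
})
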