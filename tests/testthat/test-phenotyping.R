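gate_fixture <- function(vals, markers = c("CK", "CD3", "CD4", "CD8", "CD68", "CD20")) {
  M <- matrix(rep(vals, each = 1), nrow = length(vals) / length(markers),
              byrow = TRUE, dimnames = list(NULL, markers))
  cell_table(data.frame(cell_id = sprintf("c%d", seq_len(nrow(M))),
                        case_id = "p", roi_id = "r", x_px = 1, y_px = 1,
                        area_px = 1, M, check.names = FALSE), markers)
}

test_that("gating rules assign populations first-match-wins with fall-through", {
  thr <- stats::setNames(rep(5, 6), c("CK", "CD3", "CD4", "CD8", "CD68", "CD20"))
  #            CK CD3 CD4 CD8 CD68 CD20
  cells <- gate_fixture(c(50,  1,  1,  1,  1,  1,   # tumor
                           1, 40, 30,  1,  1,  1,   # CD4 T
                           1, 40,  1, 30,  1,  1,   # CD8 T
                           1,  1,  1,  1, 30,  1,   # TAM
                           1,  1,  1,  1,  1,  1))  # nothing
  gated <- gate_populations(cells, thresholds = thr)
  expect_equal(gated$population, c("tumor", "CD4T", "CD8T", "TAM", "unassigned"))
  # partition: every cell gets exactly one label from rules + unassigned
  expect_true(all(gated$population %in%
                    c("tumor", "CD4T", "CD8T", "TAM", "B", "unassigned")))
  expect_error(gate_populations(cells, gating_scheme(list(
    list(population = "x", positive = "NOPE"))), thresholds = thr),
    "unknown markers")
})

test_that("gating recovers synthetic truth populations at 95%+", {
  cfg <- simulation_config(n_cases_per_group = 1, seed = 31)
  out <- generate_case_image(cfg, "p1", "PWH", seed = 4)
  cells <- gate_populations(segment_roi(out$image), panel = cfg$panel)
  m <- greedy_match(cbind(cells$x_px, cells$y_px),
                    cbind(out$truth$x_px, out$truth$y_px), max_dist = 2)
  acc <- mean(cells$population[m$i] == out$truth$population[m$j])
  expect_gte(acc, 0.95)
})

test_that("clustering separates well-separated phenotypes and is deterministic", {
  set.seed(42)
  X <- abs(rbind(matrix(rnorm(200 * 5, 0), 200), matrix(rnorm(200 * 5, 8), 200)))
  colnames(X) <- paste0("m", 1:5)
  ct <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:400), case_id = "a",
                              roi_id = "r", x_px = 1, y_px = 1, area_px = 1,
                              X, check.names = FALSE), paste0("m", 1:5))
  cl <- cluster_cells(ct, model = cluster_model(k_neighbors = 60))
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, rep(1:2, each = 200)), 1)
  cl2 <- cluster_cells(ct, model = cluster_model(k_neighbors = 60))
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_cells(ct[1:10, ], model = cluster_model(k_neighbors = 30)),
               "at least")
})

test_that("exact kNN matches the all-pairs oracle", {
  set.seed(9)
  X <- matrix(rnorm(50 * 4), 50)
  nn <- tmespectra:::knn_indices(X, k = 6)
  d2 <- as.matrix(dist(X))^2
  diag(d2) <- Inf
  for (i in 1:50)
    expect_identical(nn[i, ], order(d2[i, ])[1:6])
})

test_that("cluster group statistics match the exact-test oracle", {
  mkcells <- function(counts1, counts2) {
    n1 <- sum(counts1); n2 <- sum(counts2)
    df <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n1 + n2)),
      case_id = rep(c("p1", "p2"), c(n1, n2)), roi_id = "r",
      x_px = 1, y_px = 1, area_px = 1,
      population = "T",
      cluster = c(rep(seq_along(counts1), counts1),
                  rep(seq_along(counts2), counts2)),
      M = 1)
    cell_table(df, "M")
  }
  mf <- cohort_manifest(data.frame(case_id = c("p1", "p2"),
                                   group = c("g1", "g2")))
  # identical composition: all fold changes 1, all p-values 1
  st <- cluster_group_stats(mkcells(c(5, 10, 5), c(5, 10, 5)), mf, group1 = "g1")
  expect_true(all(st$fold_change == 1))
  expect_equal(st$p, rep(1, 3))
  # 2x2 table (3/10 vs 7/10) against hypergeometric enumeration
  st2 <- cluster_group_stats(mkcells(c(3, 7), c(7, 3)), mf, group1 = "g1")
  expect_equal(st2$p[1], fisher_enum_p(3, 7, 7, 3), tolerance = 1e-12)
  expect_equal(st2$p[2], fisher_enum_p(7, 3, 3, 7), tolerance = 1e-12)
  # proportions sum to one within each group
  st3 <- cluster_group_stats(mkcells(c(2, 9, 4), c(1, 1, 12)), mf)
  expect_equal(sum(st3$prop_g1), 1)
  expect_equal(sum(st3$prop_g2), 1)
  expect_true(all(st3$p_adj >= st3$p))
})

test_that("cluster heatmaps are min-max scaled per marker", {
  df <- data.frame(cell_id = sprintf("c%d", 1:6), case_id = "p", roi_id = "r",
                   x_px = 1, y_px = 1, area_px = 1,
                   cluster = rep(1:3, each = 2),
                   A = rep(c(2, 4, 6), each = 2), B = 5)
  ct <- cell_table(df, c("A", "B"))
  hm <- cluster_marker_heatmap(ct)
  expect_equal(unname(hm[, "A"]), c(0, 0.5, 1))
  expect_equal(unname(hm[, "B"]), c(0, 0, 0))   # constant marker maps to 0
  one <- cluster_marker_heatmap(ct[ct$cluster == 1, ])
  expect_true(all(one == 0))
  # random means: argmax is 1 and argmin is 0 per marker
  set.seed(12)
  ct2 <- make_cells(30, c("A", "B", "C"), seed = 12)
  ct2$cluster <- rep(1:5, each = 6)
  hm2 <- cluster_marker_heatmap(ct2)
  for (m in colnames(hm2)) {
    expect_equal(max(hm2[, m]), 1)
    expect_equal(min(hm2[, m]), 0)
  }
})

test_that("marker comparisons are null on identical groups and recover planted shifts", {
  set.seed(8)
  base <- data.frame(case = rep(sprintf("a%d", 1:3), each = 20),
                     y = rlnorm(60))
  df <- rbind(base, transform(base, case = sub("a", "b", case)))
  ct <- cell_table(data.frame(cell_id = sprintf("c%03d", seq_len(nrow(df))),
                              case_id = df$case, roi_id = "r", x_px = 1,
                              y_px = 1, area_px = 1, M = df$y,
                              check.names = FALSE), "M")
  mf <- cohort_manifest(data.frame(case_id = c(sprintf("a%d", 1:3), sprintf("b%d", 1:3)),
                                   group = rep(c("g1", "g2"), each = 3)))
  mc <- marker_group_comparison(ct, "M", mf, group1 = "g1")
  expect_equal(mc$mm_estimate, 0, tolerance = 1e-8)
  expect_equal(mc$rank_p, 1, tolerance = 1e-12)

  # parameter recovery: group shift 1.0 with case random intercepts (SD 0.5)
  one_rep <- function(seed) {
    set.seed(seed)
    n_case <- 20; n_cell <- 10
    case <- rep(sprintf("k%02d", 1:(2 * n_case)), each = n_cell)
    grp <- rep(c("g1", "g2"), each = n_case * n_cell)
    y <- rep(rnorm(2 * n_case, 0, 0.5), each = n_cell) +
      (grp == "g1") * 1.0 + rnorm(2 * n_case * n_cell) + 10
    ct <- cell_table(data.frame(cell_id = sprintf("c%05d", seq_along(y)),
                                case_id = case, roi_id = "r", x_px = 1,
                                y_px = 1, area_px = 1, M = y,
                                check.names = FALSE), "M")
    mf <- cohort_manifest(data.frame(case_id = sprintf("k%02d", 1:(2 * n_case)),
                                     group = rep(c("g1", "g2"), each = n_case)))
    marker_group_comparison(ct, "M", mf, group1 = "g1")$mm_estimate
  }
  est <- vapply(1:100, one_rep, numeric(1))
  expect_lt(abs(mean(est) - 1.0), 3 * sd(est) / sqrt(length(est)))
})

test_that("with no between-case variance the mixed model reduces to the mean difference", {
  set.seed(5)
  y <- rnorm(80, 10)
  case <- rep(sprintf("k%d", 1:8), each = 10)
  grp <- rep(c("g1", "g2"), each = 40)
  y[grp == "g1"] <- y[grp == "g1"] + 2
  ct <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:80), case_id = case,
                              roi_id = "r", x_px = 1, y_px = 1, area_px = 1,
                              M = y, check.names = FALSE), "M")
  mf <- cohort_manifest(data.frame(case_id = sprintf("k%d", 1:8),
                                   group = rep(c("g1", "g2"), each = 4)))
  mc <- marker_group_comparison(ct, "M", mf, group1 = "g1")
  expect_equal(mc$mm_estimate,
               mean(y[grp == "g1"]) - mean(y[grp == "g2"]), tolerance = 1e-6)
  expect_error(marker_group_comparison(ct, "NOPE", mf), "unknown markers")
})
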