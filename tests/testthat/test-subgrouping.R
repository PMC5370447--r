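test_that("sqrt-JSD matches direct KL arithmetic and its bounds", {
  expect_equal(sqrt_jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(sqrt_jsd(c(1, 0), c(0, 1)), 1)  # disjoint support, base 2
  p <- c(0.5, 0.5)
  q <- c(0.25, 0.75)
  expect_equal(sqrt_jsd(p, q), oracle_sqrt_jsd(p, q), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:5) {
    a <- runif(6); a <- a / sum(a)
    b <- runif(6); b <- b / sum(b)
    expect_equal(sqrt_jsd(a, b), oracle_sqrt_jsd(a, b), tolerance = 1e-12)
  }
})

test_that("JSD distance matrix is a metric with zero diagonal", {
  set.seed(13)
  m <- matrix(rnorm(20 * 12, 8, 1), nrow = 20,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:12)))
  x <- make_expr(m, roles = rep("tumour", 12))
  d <- jsd_distance_matrix(x)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 12))
  expect_true(all(d >= 0 & d <= 1))
  # identical samples at distance 0
  m2 <- cbind(m, S13 = m[, 1])
  x2 <- make_expr(m2, roles = rep("tumour", 13))
  expect_equal(jsd_distance_matrix(x2)["S01", "S13"], 0)
  # triangle inequality on 50 random triples
  for (i in 1:50) {
    tri <- sample(ncol(d), 3)
    expect_lte(d[tri[1], tri[2]],
               d[tri[1], tri[3]] + d[tri[3], tri[2]] + 1e-12)
  }
})

test_that("Ward merge heights match a hand Lance-Williams recursion", {
  set.seed(17)
  pts <- matrix(rnorm(10), ncol = 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("S", 1:5)
  wc <- ward_cluster(d)
  expect_equal(sort(wc$hclust$height), sort(oracle_ward_heights(d)),
               tolerance = 1e-10)
  expect_true(all(diff(wc$hclust$height) >= -1e-12))
})

test_that("well-separated blobs are recovered exactly and labeled by survival", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(20, 0), ncol = 2),
               matrix(rnorm(20, 5), ncol = 2))
  ids <- sprintf("S%02d", 1:20)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- ids
  truth <- rep(c("A", "B"), each = 10)
  wc <- ward_cluster(d)
  expect_equal(ari(tidy(wc)$subgroup, truth), 1)

  # blob B dies fast: it must be labeled Basal II
  clinical <- tibble::tibble(
    sample_id = ids,
    survival_time = c(rep(100, 10), rep(5, 10)),
    event = 1L)
  wc2 <- ward_cluster(d, clinical)
  lab <- as.data.frame(tidy(wc2))
  expect_true(all(lab$subgroup[1:10] == "Basal I"))
  expect_true(all(lab$subgroup[11:20] == "Basal II"))
})

test_that("generator cohorts cluster to truth on the planted survival probes", {
  co <- generate_cohort(seed = 101, n_mirna = 4, n_mirna_diff = 0,
                        n_cytobands = 5)
  d <- jsd_distance_matrix(co$expr, probes = unlist(co$truth$signature))
  wc <- ward_cluster(d, co$clinical)
  lab <- tidy(wc)
  expect_gte(ari(lab$subgroup, co$truth$subgroup[lab$sample_id]), 0.8)
  # hazard_ratio = 3: the longer-surviving cluster is Basal I, which is the
  # planted Basal I
  agree <- mean(lab$subgroup == co$truth$subgroup[lab$sample_id])
  expect_gte(agree, 0.9)
})

test_that("signature refinement matches exact enumeration and recovers truth", {
  # exact two-sided p on a 3 vs 3 fixture
  m <- rbind(probe = c(3, 4, 5, 0, 1, 2),
             null1 = c(1, 3, 2, 2, 1, 3),
             null2 = c(5, 1, 4, 2, 6, 3))
  colnames(m) <- paste0("S", 1:6)
  x <- make_expr(m, roles = rep("tumour", 6))
  labels <- tibble::tibble(sample_id = paste0("S", 1:6),
                           subgroup = rep(c("Basal I", "Basal II"), each = 3))
  sig <- refine_signature(x, labels, threshold = 1)
  expect_equal(sig$p_value[sig$probe_id == "probe"], 2 / 20)
  # two-sided test is symmetric in the subgroup labels
  sig2 <- refine_signature(x, tibble::tibble(
    sample_id = labels$sample_id,
    subgroup = ifelse(labels$subgroup == "Basal I", "Basal II", "Basal I")),
    threshold = 1)
  expect_equal(sig$p_value[order(sig$probe_id)],
               sig2$p_value[order(sig2$probe_id)])
})

test_that("planted signature probes dominate the recovered signature", {
  co <- generate_cohort(n_signature = c(G1 = 30, G2 = 30, G3 = 20),
                        n_mirna = 4, n_mirna_diff = 0, n_cytobands = 5,
                        seed = 7)
  d <- jsd_distance_matrix(co$expr, probes = unlist(co$truth$signature))
  wc <- ward_cluster(d, co$clinical)
  sig <- refine_signature(
    expr_subset(co$expr, samples = tumour_ids(co$expr)), wc)
  planted <- unlist(co$truth$signature)
  recovered <- signature_probes(sig)
  expect_gte(mean(planted %in% recovered), 0.9)
})

test_that("permuted labels yield no planted enrichment beyond chance", {
  co <- generate_cohort(n_tumour = 60, n_control = 10, n_probes = 200,
                        n_diff = c(a = 0, b = 0, c = 0),
                        n_signature = c(G1 = 10, G2 = 10, G3 = 10),
                        n_mirna = 4, n_mirna_diff = 0, n_cytobands = 5,
                        seed = 67)
  planted <- unlist(co$truth$signature)
  tum <- tumour_ids(co$expr)
  hits <- numeric(20)
  set.seed(99)
  for (i in 1:20) {
    perm <- tibble::tibble(
      sample_id = tum,
      subgroup = sample(rep(c("Basal I", "Basal II"), c(20, 40))))
    sig <- suppressWarnings(refine_signature(
      expr_subset(co$expr, samples = tum), perm))
    rec <- signature_probes(sig)
    hits[i] <- if (length(rec)) mean(rec %in% planted) else 0
  }
  # planted fraction of the pool is 30/200 = 0.15; permuted labels should
  # select planted probes at about that chance rate
  expect_lt(mean(hits), 0.3)
})

test_that("probe blocks are recovered and named by their expression pattern", {
  # three perfectly internally-correlated blocks, zero cross-correlation
  set.seed(5)
  base <- matrix(rnorm(3 * 12), nrow = 3)
  m <- base[rep(1:3, each = 4), ] + matrix(rnorm(12 * 12, 0, 1e-6), 12)
  rownames(m) <- sprintf("P%02d", 1:12)
  colnames(m) <- sprintf("S%02d", 1:12)
  x <- make_expr(m, roles = rep("tumour", 12))
  labels <- tibble::tibble(sample_id = colnames(m),
                           subgroup = rep(c("Basal I", "Basal II"), 6))
  out <- group_probes(x, rownames(m), labels)
  expect_equal(length(unique(out$block[1:4])), 1)
  expect_equal(length(unique(out$block[5:8])), 1)
  expect_equal(length(unique(out$block[9:12])), 1)
  expect_setequal(unique(out$block), c("G1", "G2", "G3"))

  # planted generator blocks recovered with the direction-based names
  co <- generate_cohort(n_mirna = 4, n_mirna_diff = 0, n_cytobands = 5,
                        seed = 71)
  truth_labels <- tibble::tibble(sample_id = names(co$truth$subgroup),
                                 subgroup = unname(co$truth$subgroup))
  out2 <- group_probes(co$expr, unlist(co$truth$signature), truth_labels)
  truth_block <- rep(c("G1", "G2", "G3"),
                     lengths(co$truth$signature))
  expect_gte(mean(out2$block == truth_block), 0.95)
})

test_that("Spearman distance of a probe with itself is zero", {
  set.seed(2)
  m <- matrix(rnorm(30), nrow = 5,
              dimnames = list(paste0("P", 1:5), paste0("S", 1:6)))
  x <- make_expr(m, roles = rep("tumour", 6))
  d <- correlation_distance(x)
  expect_equal(unname(diag(d)), rep(0, 5))
})
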