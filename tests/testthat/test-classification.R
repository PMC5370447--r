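two_group_labels <- function(ids, n_I) {
  tibble::tibble(sample_id = ids,
                 subgroup = rep(c("Basal I", "Basal II"),
                                c(n_I, length(ids) - n_I)))
}

test_that("centroids are per-probe subgroup means", {
  set.seed(31)
  m <- matrix(rnorm(20 * 30, 8), nrow = 20,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:30)))
  x <- make_expr(m, roles = rep("tumour", 30))
  labels <- two_group_labels(colnames(m), 12)
  cen <- compute_centroids(x, labels, rownames(m))
  # brute-force per-probe sum / n oracle
  for (p in rownames(m)) {
    expect_equal(cen$basal_I[cen$probe_id == p],
                 sum(m[p, 1:12]) / 12, tolerance = 1e-12)
    expect_equal(cen$basal_II[cen$probe_id == p],
                 sum(m[p, 13:30]) / 18, tolerance = 1e-12)
  }
  # one sample per subgroup: centroid equals that sample
  x2 <- expr_subset(x, samples = c("S01", "S13"))
  cen2 <- compute_centroids(x2, labels, rownames(m))
  expect_equal(cen2$basal_I, unname(m[, "S01"]))
  expect_equal(cen2$basal_II, unname(m[, "S13"]))
  # {1, 3} averages to 2
  m3 <- matrix(c(1, 3, 9, 9), nrow = 2, byrow = TRUE,
               dimnames = list(c("P", "Q"), c("A", "B")))
  x3 <- make_expr(m3, roles = rep("tumour", 2))
  labs3 <- tibble::tibble(sample_id = c("A", "B"),
                          subgroup = c("Basal I", "Basal I"))
  expect_error(compute_centroids(x3, labs3, "P"), "non-empty")
  expect_error(compute_centroids(x, labels, c("P01", "NOPE")), "NOPE")
})

test_that("standardization divides by the reference mean and is idempotent-guarded", {
  m <- matrix(c(6, 6, 3, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("Pa", "Pb"), c("S1", "S2")))
  x <- make_expr(m, roles = rep("tumour", 2))
  s <- standardize(x)
  expect_equal(unname(expr_values(s)["Pa", ]), c(1, 1))  # 6 / mean 6
  expect_true(attr(s, "standardized"))
  expect_equal(attr(s, "reference_n"), 2)
  expect_error(standardize(s), "already")

  # per-probe mean of the standardized reference matrix is exactly 1
  set.seed(5)
  big <- matrix(rexp(50 * 20) + 1, nrow = 50,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:20)))
  xb <- make_expr(big, roles = rep("tumour", 20))
  sb <- standardize(xb)
  expect_equal(unname(rowMeans(expr_values(sb))), rep(1, 50),
               tolerance = 1e-12)

  # non-positive reference mean is rejected with the probe named
  neg <- matrix(c(-1, -2), nrow = 1, dimnames = list("Pneg", c("S1", "S2")))
  expect_error(standardize(make_expr(neg, roles = rep("tumour", 2))), "Pneg")
})

test_that("assignment picks the minimal Euclidean distance with Basal I ties", {
  cen <- tibble::tibble(probe_id = c("P1", "P2"),
                        basal_I = c(0, 0), basal_II = c(4, 0))
  class(cen) <- c("centroid_set", class(cen))
  attr(cen, "standardized") <- FALSE
  m <- cbind(atII = c(4, 0), mid = c(2, 5), nearI = c(0.5, 0))
  rownames(m) <- c("P1", "P2")
  x <- make_expr(m, roles = rep("tumour", 3))
  a <- assign_subgroups(x, cen)
  expect_equal(a$label, c("Basal II", "Basal I", "Basal I"))
  expect_equal(a$distance_to_I[a$sample_id == "atII"], 4)
  expect_equal(a$distance_to_II[a$sample_id == "atII"], 0)
  expect_true(a$tie_flag[a$sample_id == "mid"])
  expect_false(any(a$tie_flag[a$sample_id != "mid"]))
})

test_that("labels match a brute-force two-distance comparison on random data", {
  set.seed(41)
  m <- matrix(rnorm(10 * 50), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("S%02d", 1:50)))
  cen <- tibble::tibble(probe_id = rownames(m),
                        basal_I = rnorm(10), basal_II = rnorm(10))
  class(cen) <- c("centroid_set", class(cen))
  attr(cen, "standardized") <- FALSE
  x <- make_expr(m, roles = rep("tumour", 50))
  a <- assign_subgroups(x, cen)
  for (i in 1:50) {
    dI <- sqrt(sum((m[, i] - cen$basal_I)^2))
    dII <- sqrt(sum((m[, i] - cen$basal_II)^2))
    expect_equal(a$label[i], if (dI <= dII) "Basal I" else "Basal II")
    expect_equal(a$distance_to_I[i], dI, tolerance = 1e-12)
  }
})

test_that("standardization-state mismatch is rejected", {
  m <- matrix(rexp(4) + 1, 2, dimnames = list(c("P1", "P2"), c("S1", "S2")))
  x <- make_expr(m, roles = rep("tumour", 2))
  cen <- compute_centroids(x, tibble::tibble(sample_id = c("S1", "S2"),
                                             subgroup = c("Basal I",
                                                          "Basal II")),
                           c("P1", "P2"))
  expect_error(assign_subgroups(standardize(x), cen), "mismatch")
})

test_that("assignment is invariant to probe-wise platform rescaling after standardization", {
  set.seed(53)
  co <- generate_cohort(n_tumour = 60, n_control = 10, n_probes = 40,
                        n_diff = c(a = 0, b = 0, c = 0),
                        n_signature = c(G1 = 15, G2 = 15, G3 = 10),
                        n_mirna = 4, n_mirna_diff = 0, n_cytobands = 5,
                        seed = 53)
  sig <- unlist(co$truth$signature)
  labels <- tibble::tibble(sample_id = names(co$truth$subgroup),
                           subgroup = unname(co$truth$subgroup))
  tum <- expr_subset(co$expr, samples = tumour_ids(co$expr))
  cen <- compute_centroids(co$expr, labels, sig)
  cen_std <- standardize(cen, reference = co$expr,
                         reference_samples = tumour_ids(co$expr))
  base <- assign_subgroups(standardize(tum), cen_std)

  # simulate a platform with arbitrary probe-wise positive scale factors
  scale <- runif(length(sig), 0.2, 5)
  m2 <- expr_values(tum)[sig, ] * scale
  other <- make_expr(m2, roles = rep("tumour", ncol(m2)), platform = "other")
  rescaled <- assign_subgroups(standardize(other), cen_std)
  expect_equal(rescaled$label, base$label)
  expect_equal(rescaled$distance_to_I, base$distance_to_I, tolerance = 1e-9)
})

test_that("held-out centroid assignment recovers planted subgroups", {
  agree <- numeric(5)
  for (i in 1:5) {
    co <- generate_cohort(n_mirna = 4, n_mirna_diff = 0, n_cytobands = 5,
                          seed = 300 + i)
    sig <- unlist(co$truth$signature)
    truth <- co$truth$subgroup
    tum <- tumour_ids(co$expr)
    train <- tum[seq_along(tum) %% 2 == 1]
    test <- setdiff(tum, train)
    labels <- tibble::tibble(sample_id = train,
                             subgroup = unname(truth[train]))
    cen <- compute_centroids(expr_subset(co$expr, samples = train),
                             labels, sig)
    a <- assign_subgroups(expr_subset(co$expr, probes = sig, samples = test),
                          cen)
    agree[i] <- mean(a$label == truth[a$sample_id])
  }
  expect_gte(min(agree), 0.9)
})

test_that("probe mapping keeps one lexicographic target and reports drops", {
  ann <- tibble::tibble(
    source_probe = c("P1", "P2", "P2", "P3"),
    gene = c("A", "B", "B", "C"),
    target_probe = c("T1", "B_2", "A_1", "T3"))
  sig <- c("P1", "P2", "P3", "P4", "P5")
  mp <- map_probes(sig, ann)
  expect_equal(nrow(mp), 3)
  expect_equal(mp$target_probe[mp$probe_id == "P2"], "A_1")
  rep <- attr(mp, "report")
  expect_equal(rep$matched, 3)
  expect_setequal(rep$dropped, c("P4", "P5"))

  # identity table retains everything
  ident <- tibble::tibble(source_probe = sig, target_probe = sig)
  expect_equal(nrow(map_probes(sig, ident)), 5)

  # empty intersection errors
  expect_error(map_probes(c("Q1"), ann), "no probes mapped")
})
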