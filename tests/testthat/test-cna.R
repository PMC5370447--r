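states_fixture <- function() {
  tidyr::expand_grid(sample_id = sprintf("S%d", 1:4),
                     cytoband = c("chr1q11", "chr1q12")) |>
    dplyr::mutate(state = "neutral")
}

test_that("five-state calls collapse to the three-state alphabet", {
  st <- tibble::tibble(
    sample_id = "S1",
    cytoband = paste0("b", 1:5),
    state = c("homdel", "hetdel", "neutral", "gain", "amp"))
  out <- collapse_states(st)
  expect_equal(out$state, c("loss", "loss", "neutral", "gain", "gain"))
  bad <- st
  bad$state[2] <- "weird"
  expect_error(collapse_states(bad), "weird.*S1.*b2")
})

test_that("cytoband rates are direct tallies per subgroup", {
  st <- states_fixture()
  st$state[st$sample_id == "S1" & st$cytoband == "chr1q11"] <- "gain"
  st$state[st$cytoband == "chr1q12"] <- "loss"
  labels <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                           subgroup = rep(c("Basal I", "Basal II"), each = 2))
  r <- cytoband_rates(st, labels)
  expect_equal(r$gain_rate[r$cytoband == "chr1q11" &
                           r$subgroup == "Basal I"], 0.5)
  expect_equal(r$loss_rate[r$cytoband == "chr1q12" &
                           r$subgroup == "Basal II"], 1)
  # random fixture against a brute-force tally
  set.seed(31)
  st2 <- tidyr::expand_grid(sample_id = sprintf("S%02d", 1:10),
                            cytoband = sprintf("b%d", 1:6)) |>
    dplyr::mutate(state = sample(c("loss", "neutral", "gain"), 60,
                                 replace = TRUE))
  lab2 <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                         subgroup = rep(c("Basal I", "Basal II"), 5))
  r2 <- cytoband_rates(st2, lab2)
  for (i in sample(nrow(r2), 5)) {
    ids <- lab2$sample_id[lab2$subgroup == r2$subgroup[i]]
    sub <- st2[st2$cytoband == r2$cytoband[i] & st2$sample_id %in% ids, ]
    expect_equal(r2$gain_rate[i], mean(sub$state == "gain"))
    expect_equal(r2$loss_rate[i], mean(sub$state == "loss"))
  }
})

test_that("binomial enrichment p-values match closed forms and the pmf sum", {
  expect_equal(binom_twosided(4, 4, 0.5), 0.125)
  expect_equal(binom_twosided(2, 4, 0.5), 1)  # symmetric centre, capped
  # k = 7, n = 20, p0 = 0.2 against a direct pmf tail sum
  upper <- sum(dbinom(7:20, 20, 0.2))
  lower <- sum(dbinom(0:7, 20, 0.2))
  expect_equal(binom_twosided(7, 20, 0.2), min(1, 2 * min(upper, lower)),
               tolerance = 1e-12)
})

test_that("binomial tail sums agree with Monte-Carlo permutation of the null", {
  set.seed(37)
  n <- 25
  p0 <- 0.3
  k <- 12
  draws <- rbinom(1e5, n, p0)
  upper_mc <- mean(draws >= k)
  upper_exact <- sum(dbinom(k:n, n, p0))
  mc_se <- sqrt(upper_exact * (1 - upper_exact) / 1e5)
  expect_lt(abs(upper_mc - upper_exact), 3 * mc_se)
})

test_that("per-band tests pool the rate across subgroups and flag untestable bands", {
  st <- states_fixture()  # all neutral: p0 = 0 for both types
  labels <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                           subgroup = rep(c("Basal I", "Basal II"), each = 2))
  out <- cytoband_binomial(st, labels)
  expect_true(all(!out$testable))
  expect_true(all(is.na(out$p_value)))

  st$state[st$sample_id %in% c("S1", "S2") & st$cytoband == "chr1q11"] <- "gain"
  out2 <- cytoband_binomial(st, labels)
  row <- out2[out2$cytoband == "chr1q11" & out2$type == "gain" &
              out2$subgroup == "Basal I", ]
  expect_true(row$testable)
  expect_equal(row$p0, 0.5)
  expect_equal(row$p_value, binom_twosided(2, 2, 0.5))
})

test_that("PGA is a length-weighted percentage with correct trivials", {
  bands <- tibble::tibble(cytoband = c("b1", "b2", "b3"),
                          length_bp = c(30e6, 1470e6, 1500e6))
  st <- tidyr::expand_grid(sample_id = c("S1", "S2"),
                           cytoband = bands$cytoband) |>
    dplyr::mutate(state = "neutral")
  st$state[st$sample_id == "S2" & st$cytoband == "b1"] <- "gain"
  out <- pga(st, bands)
  expect_equal(out$pga_gain[out$sample_id == "S1"], 0)
  expect_equal(out$pga_loss[out$sample_id == "S1"], 0)
  expect_equal(out$pga_gain[out$sample_id == "S2"], 1)  # 30 Mb of 3000 Mb
})

test_that("PGA is invariant to subdividing a band into equal-state halves", {
  set.seed(41)
  bands <- tibble::tibble(cytoband = sprintf("b%d", 1:5),
                          length_bp = c(10, 20, 30, 40, 50) * 1e6)
  st <- tidyr::expand_grid(sample_id = sprintf("S%d", 1:6),
                           cytoband = bands$cytoband) |>
    dplyr::mutate(state = sample(c("loss", "neutral", "gain"), 30,
                                 replace = TRUE))
  base <- pga(st, bands)
  # split b3 into two 15 Mb halves with identical states
  bands2 <- dplyr::bind_rows(
    bands[bands$cytoband != "b3", ],
    tibble::tibble(cytoband = c("b3a", "b3b"), length_bp = 15e6))
  st2 <- dplyr::bind_rows(
    st[st$cytoband != "b3", ],
    st[st$cytoband == "b3", ] |> dplyr::mutate(cytoband = "b3a"),
    st[st$cytoband == "b3", ] |> dplyr::mutate(cytoband = "b3b"))
  split <- pga(st2, bands2)
  merged <- dplyr::inner_join(base, split, by = "sample_id")
  expect_equal(merged$pga_gain.x, merged$pga_gain.y, tolerance = 1e-12)
  expect_equal(merged$pga_loss.x, merged$pga_loss.y, tolerance = 1e-12)
})

test_that("a planted gain-probability contrast yields higher Basal II PGA", {
  co <- generate_cohort(n_mirna = 4, n_mirna_diff = 0, n_cytobands = 100,
                        seed = 43)
  labels <- tibble::tibble(sample_id = names(co$truth$subgroup),
                           subgroup = unname(co$truth$subgroup))
  out <- pga(co$cna, co$cytobands, labels)
  means <- tapply(out$pga_gain, out$subgroup, mean)
  expect_gt(means[["Basal II"]], means[["Basal I"]])
  test <- attr(out, "subgroup_test")
  expect_lt(test$p_value[test$type == "gain"], 0.01)
})

test_that("a sample contributes one state per band", {
  st <- states_fixture()
  st$state[st$sample_id == "S1"] <- "gain"
  labels <- tibble::tibble(sample_id = sprintf("S%d", 1:4),
                           subgroup = rep(c("Basal I", "Basal II"), each = 2))
  r <- cytoband_rates(st, labels)
  expect_true(all(r$gain_count + r$loss_count <= r$n))
})

test_that("segment quantization takes the majority-overlap state", {
  bands <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 10e6,
                          band_name = "q11", stain = "gneg",
                          cytoband = "chr1q11", length_bp = 10e6)
  segs <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                         start_bp = c(0, 6e6), end_bp = c(6e6, 10e6),
                         state = c("gain", "neutral"))
  out <- quantize_segments(segs, bands)
  expect_equal(out$state, "gain")
  # exact tie resolves to neutral
  segs2 <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                          start_bp = c(0, 5e6), end_bp = c(5e6, 10e6),
                          state = c("gain", "loss"))
  expect_equal(quantize_segments(segs2, bands)$state, "neutral")
})
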