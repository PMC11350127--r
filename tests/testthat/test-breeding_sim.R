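test_that("achiasmatic gametes are uniform over the 2^n genotype classes", {
  set.seed(101)
  n_draws <- 50000
  panel <- dh_panel(n_draws, n_chrom = 5)
  ids <- apply(panel_matrix(panel), 1, genotype_id)
  # all-Col frequency within 3 binomial SDs of 1/32
  p0 <- 1 / 32
  phat <- mean(ids == "CSL_CCCCC")
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n_draws))
  # chi-square goodness of fit over all 32 classes not rejected at 0.01
  obs <- table(factor(ids, levels = enumerate_panel(5)$line_id))
  pval <- stats::chisq.test(obs, p = rep(p0, 32))$p.value
  expect_gt(pval, 0.01)
  expect_error(dh_panel(0), "positive")
})

test_that("single-chromosome gametes are a fair coin", {
  set.seed(102)
  g <- replicate(10000, achiasmatic_gamete(1))
  expect_lt(abs(mean(g == "Col") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("panel completeness reporting is an exact set difference", {
  full <- enumerate_panel(5)
  expect_equal(nrow(panel_completeness(full)), 0L)
  drop_col <- full[full$line_id != "CSL_CCCCC", ]
  miss <- panel_completeness(drop_col)
  expect_equal(miss$line_id, "CSL_CCCCC")
})

test_that("simulated completeness matches the inclusion-exclusion closed form", {
  set.seed(103)
  n_sims <- 400
  for (n_lines in c(64, 96)) {
    hits <- replicate(n_sims, nrow(panel_completeness(dh_panel(n_lines, 5))) == 0L)
    p_exact <- coupon_collector_exact(n_lines, 32)
    expect_equal(completeness_probability(n_lines, 5), p_exact, tolerance = 1e-12)
    se <- sqrt(p_exact * (1 - p_exact) / n_sims)
    expect_lt(abs(mean(hits) - p_exact), 3 * se)
  }
  # monotone in the number of lines
  probs <- vapply(c(32, 64, 96, 128), completeness_probability, 0, n_chrom = 5)
  expect_true(all(diff(probs) > 0))
})

test_that("recombination fraction between two markers follows Haldane", {
  d <- 20
  map <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, d))
  pa <- c("Col", "Col"); pb <- c("Ler", "Ler")
  set.seed(104)
  n <- 40000
  rec <- replicate(n, {
    g <- recombinant_gamete(pa, pb, map)
    g[1] != g[2]
  })
  c_exp <- haldane_c(d)
  expect_lt(abs(mean(rec) - c_exp), 3 * sqrt(c_exp * (1 - c_exp) / n))
  # co-located markers never recombine; identical parents are invariant
  map0 <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(10, 10))
  set.seed(105)
  g0 <- replicate(200, recombinant_gamete(pa, pb, map0))
  expect_true(all(g0[1, ] == g0[2, ]))
  expect_identical(recombinant_gamete(pa, pa, map), pa)
  expect_error(recombinant_gamete(pa, c("Ler"), map), "match the marker map")
})

test_that("NIL panels segregate only the target chromosome", {
  map <- tiny_map(c(100, 80))
  scsl <- c("Ler", "Col"); recurrent <- c("Col", "Col")
  set.seed(106)
  nils <- nil_panel(scsl, recurrent, 40, map)
  m <- marker_matrix(nils, map)
  expect_true(all(m[, map$chrom == 2] == "Col"))
  expect_true(any(m[, map$chrom == 1] == "Ler"))
  expect_error(nil_panel(c("Ler", "Ler"), recurrent, 5, map),
               "exactly one chromosome")
})

test_that("fraction of NILs with a visible crossover matches the Poisson zero class", {
  # dense map so essentially every crossover is visible at marker resolution
  map <- default_marker_map(1, 100, spacing_cM = 1)
  set.seed(107)
  nils <- nil_panel("Ler", "Col", 2000, map)
  m <- marker_matrix(nils, map)
  n_alleles <- apply(m, 1, function(v) length(unique(v)))
  phat <- mean(n_alleles > 1)
  p0 <- 1 - exp(-1)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 2000) + 0.01)
})

test_that("introgression boundaries bracket the donor segment", {
  pos <- seq(0, 50, by = 10)
  alleles <- c("Col", "Col", "Ler", "Ler", "Col", "Col")
  b <- introgression_boundaries(alleles, pos, donor = "Ler")
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_marker, 20)
  expect_equal(b$end_marker, 30)
  expect_equal(b$start_flank, 10)
  expect_equal(b$end_flank, 40)
  expect_equal(b$start_mid, 15)
  expect_equal(b$end_mid, 35)
  expect_equal(nrow(introgression_boundaries(rep("Col", 6), pos, "Ler")), 0L)
})

test_that("RIL adjacent-marker recombination matches the selfing expansion", {
  d <- 10
  map <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, d))
  set.seed(108)
  n <- 50000
  rils <- ril_panel(n, map)
  m <- marker_matrix(rils, map)
  rhat <- mean(m[, 1] != m[, 2])
  r_exp <- ril_recomb(d)
  expect_equal(r_exp, 2 * haldane_c(d) / (1 + 2 * haldane_c(d)), tolerance = 1e-12)
  expect_lt(abs(rhat - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
  # limit: unlinked loci approach R = 1/2
  expect_equal(ril_recomb(1e9), 0.5, tolerance = 1e-9)
  # markers on different chromosomes are independent
  map2 <- data.frame(marker = c("a", "b"), chrom = c(1, 2), cM = c(0, 0))
  set.seed(109)
  m2 <- origin_indicator(marker_matrix(ril_panel(10000, map2), map2))
  expect_lt(abs(cor(m2[, 1], m2[, 2])), 3 / sqrt(10000))
})

test_that("identical seeds reproduce identical panels byte for byte", {
  map <- tiny_map()
  set.seed(42); a <- ril_panel(25, map)
  set.seed(42); b <- ril_panel(25, map)
  expect_identical(a, b)
  set.seed(42); pa <- dh_panel(50, 5)
  set.seed(42); pb <- dh_panel(50, 5)
  expect_identical(pa, pb)
})

test_that("map functions behave at the limits and order correctly", {
  expect_equal(haldane_c(0), 0)
  expect_equal(kosambi_c(0), 0)
  expect_equal(haldane_c(1e9), 0.5, tolerance = 1e-12)
  expect_equal(kosambi_c(1e9), 0.5, tolerance = 1e-12)
  # Kosambi maps a given distance to a larger recombination fraction than
  # Haldane at short range (interference)
  expect_gt(kosambi_c(10), haldane_c(10))
  expect_gt(ril_recomb(10, "kosambi"), ril_recomb(10, "haldane"))
})
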