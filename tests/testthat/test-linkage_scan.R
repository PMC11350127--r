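test_that("dosages are exact at markers and interpolate between them", {
  map <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, 20))
  panel <- data.frame(line_id = c("l1", "l2", "l3", "l4"), panel = "RIL",
                      a = c("Col", "Col", "Ler", "Ler"),
                      b = c("Col", "Ler", "Col", "Ler"),
                      stringsAsFactors = FALSE, check.names = FALSE)
  pred <- genetic_predictors(panel, map, step_cM = 5)
  expect_true(all(pred$grid$cM == c(0, 5, 10, 15, 20)))
  # at markers: observed 0/1
  expect_equal(unname(pred$dosage[, "c1_0"]), c(1, 1, 0, 0))
  expect_equal(unname(pred$dosage[, "c1_20"]), c(1, 0, 1, 0))
  # midpoint of discordant flanks is exactly 1/2 by symmetry
  expect_equal(unname(pred$dosage[c("l2", "l3"), "c1_10"]), c(0.5, 0.5))
  # concordant flanks pull the midpoint towards the shared allele
  expect_gt(pred$dosage["l1", "c1_10"], 0.9)
  expect_lt(pred$dosage["l4", "c1_10"], 0.1)
  # closed-form conditional from the two-marker RIL haplotype distribution
  for (q in c(5, 15)) {
    for (i in 1:4) {
      xL <- as.numeric(panel$a[i] == "Col"); xR <- as.numeric(panel$b[i] == "Col")
      expect_equal(unname(pred$dosage[i, paste0("c1_", q)]),
                   ril_conditional_brute(xL, xR, q - 0, 20 - q),
                   tolerance = 1e-12)
    }
  }
})

test_that("dosage interpolation matches empirical RIL frequencies", {
  # simulate on a 3-marker map, predict the middle marker from the outer two
  map3 <- data.frame(marker = c("a", "m", "b"), chrom = 1, cM = c(0, 5, 20))
  set.seed(501)
  rils <- ril_panel(40000, map3)
  m <- origin_indicator(marker_matrix(rils, map3))
  map2 <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, 20))
  pred <- genetic_predictors(rils[, c("line_id", "panel", "a", "b")], map2,
                             step_cM = 5)
  for (xa in 0:1) for (xb in 0:1) {
    sel <- m[, 1] == xa & m[, 3] == xb
    emp <- mean(m[sel, 2])
    theo <- pred$dosage[which(sel)[1], "c1_5"]
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / sum(sel)))
  }
})

test_that("Li-Ji effective test count handles the canonical cases", {
  # two perfectly correlated markers collapse to one effective test
  map <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, 0))
  panel <- data.frame(line_id = sprintf("l%d", 1:20), panel = "RIL",
                      a = rep(c("Col", "Ler"), 10), b = rep(c("Col", "Ler"), 10),
                      stringsAsFactors = FALSE, check.names = FALSE)
  expect_equal(li_ji_threshold(panel, map)$M_eff, 1, tolerance = 1e-8)
  # orthogonal markers count fully
  set.seed(502)
  k <- 4
  x <- matrix(rep(c("Col", "Ler"), length.out = 16 * k), 16, k)
  # build exactly orthogonal columns from a Hadamard-like pattern
  h <- cbind(rep(0:1, each = 8), rep(rep(0:1, each = 4), 2),
             rep(rep(0:1, each = 2), 4), rep(0:1, 8))
  x <- ifelse(h == 1, "Col", "Ler")
  colnames(x) <- paste0("m", 1:k)
  mapk <- data.frame(marker = paste0("m", 1:k), chrom = 1, cM = seq(0, 30, 10))
  pk <- data.frame(line_id = sprintf("l%d", 1:16), panel = "RIL", x,
                   stringsAsFactors = FALSE, check.names = FALSE)
  expect_equal(li_ji_threshold(pk, mapk)$M_eff, k, tolerance = 1e-8)
  # eigen formula agrees with an independent decomposition
  map5 <- tiny_map()
  set.seed(503)
  rils <- ril_panel(80, map5)
  res <- li_ji_threshold(rils, map5)
  xm <- origin_indicator(marker_matrix(rils, map5))
  meff2 <- sum(vapply(unique(map5$chrom), function(kk) {
    lam <- svd(scale(xm[, map5$chrom == kk]))$d^2 / (nrow(xm) - 1)
    sum((lam >= 1) + (lam - floor(lam)))
  }, 0))
  expect_equal(res$M_eff, meff2, tolerance = 1e-8)
  expect_lte(res$M_eff, nrow(map5))
  # Sidak per-test level
  expect_equal(res$alpha_per_test, 1 - 0.95^(1 / res$M_eff), tolerance = 1e-12)
  # monomorphic markers are dropped with a warning
  rils2 <- rils
  rils2[[map5$marker[1]]] <- "Col"
  expect_warning(li_ji_threshold(rils2, map5), "monomorphic")
})

test_that("a noiseless marker phenotype peaks exactly at its marker", {
  map <- tiny_map()
  set.seed(504)
  rils <- ril_panel(80, map)
  y <- simulate_qtl_phenotype(rils, map, data.frame(chrom = 2, cM = 30, effect = 1),
                              sigma_e = 0)
  pred <- genetic_predictors(rils, map)
  prof <- scan_qtl(y, pred)
  pk <- prof[which.max(prof$minus_log10_p), ]
  expect_equal(pk$chrom, 2)
  expect_equal(pk$cM, 30)
  expect_gt(pk$minus_log10_p, 50)
  # profile is invariant under translation and scale-equivariant in effect
  # (checked away from the degenerate zero-residual fit)
  set.seed(509)
  yn <- simulate_qtl_phenotype(rils, map,
                               data.frame(chrom = 2, cM = 30, effect = 1),
                               sigma_e = 0.5)
  profn <- scan_qtl(yn, pred)
  prof2 <- scan_qtl(yn + 100, pred)
  expect_equal(prof2$minus_log10_p, profn$minus_log10_p, tolerance = 1e-8)
  prof3 <- scan_qtl(yn * 3, pred)
  expect_equal(prof3$minus_log10_p, profn$minus_log10_p, tolerance = 1e-8)
  expect_equal(prof3$effect, profn$effect * 3, tolerance = 1e-8)
})

test_that("iterated CIM is stable and order-invariant for two unlinked QTLs", {
  map <- tiny_map(c(80, 80))
  set.seed(505)
  rils <- ril_panel(150, map)
  qtl <- data.frame(chrom = c(1, 2), cM = c(30, 50), effect = c(1, 1))
  y <- simulate_qtl_phenotype(rils, map, qtl, sigma_e = 0.7)
  pred <- genetic_predictors(rils, map)
  thr <- li_ji_threshold(rils, map)$threshold
  res <- cim_iterate(y, pred, thr)
  expect_true(res$stable)
  expect_equal(nrow(res$qtls), 2L)
  expect_setequal(res$qtls$chrom, c(1, 2))
  expect_true(all(abs(res$qtls$peak_cM - c(30, 50)) <= 10))
  expect_true(all(res$qtls$sign == "+Col"))
  # single-QTL case: one round suffices, a second adds nothing
  set.seed(506)
  y1 <- simulate_qtl_phenotype(rils, map, qtl[1, ], sigma_e = 0.7)
  r1 <- cim_iterate(y1, pred, thr)
  expect_true(res$stable)
  expect_equal(nrow(r1$qtls), 1L)
  # null data: no QTLs
  set.seed(507)
  y0 <- setNames(rnorm(150), rils$line_id)
  r0 <- cim_iterate(y0, pred, thr)
  expect_equal(nrow(r0$qtls), 0L)
})

test_that("support intervals follow the drop-2 geometry", {
  # symmetric triangle with slope 1 per cM: interval is peak +/- 2
  cM <- 0:20
  prof <- data.frame(chrom = 1, cM = cM, minus_log10_p = 10 - abs(cM - 10))
  si <- support_interval(prof, 10, drop = 2)
  expect_equal(si$left_cM, 8)
  expect_equal(si$right_cM, 12)
  # flat profile spans the whole chromosome
  flat <- data.frame(chrom = 1, cM = cM, minus_log10_p = rep(5, 21))
  si2 <- support_interval(flat, 10, drop = 2)
  expect_equal(si2$left_cM, 0)
  expect_equal(si2$right_cM, 20)
  # bp interpolation is linear on the map
  map <- data.frame(marker = c("a", "b"), chrom = 1, cM = c(0, 20),
                    bp = c(0, 2e6))
  si3 <- support_interval(prof, 10, drop = 2, map = map)
  expect_equal(si3$left_bp, 8e5)
  expect_equal(si3$right_bp, 1.2e6)
  expect_error(support_interval(prof, 9.5), "not on the profile grid")
})

test_that("NIL fine-mapping localises the locus and propagates sign flips", {
  map <- default_marker_map(5)
  set.seed(508)
  nilC <- nil_panel(c("Col", "Col", "Col", "Col", "Ler"), rep("Col", 5), 60, map)
  nilL <- nil_panel(c("Ler", "Ler", "Ler", "Ler", "Col"), rep("Ler", 5), 60, map)
  loc_pheno <- function(panel, effect) {
    m <- marker_matrix(panel, map)
    j <- which(map$chrom == 5 & map$cM == 45)
    setNames(effect * origin_indicator(m[, j]) + rnorm(nrow(m), sd = 0.4),
             panel$line_id)
  }
  ns <- nil_scan(list(Col = nilC, Ler = nilL),
                 list(Col = loc_pheno(nilC, -2), Ler = loc_pheno(nilL, 2)), map)
  expect_true(all(c("Col", "Ler") %in% ns$table$background))
  for (bg in c("Col", "Ler")) {
    iv <- ns$intervals[[bg]]
    expect_false(is.null(iv))
    expect_true(iv$left_cM <= 45 && iv$right_cM >= 45)
  }
  # opposite-sign truths give opposite-sign peak effects
  peakC <- ns$table[ns$table$background == "Col", ]
  peakL <- ns$table[ns$table$background == "Ler", ]
  eC <- peakC$effect[which.max(peakC$minus_log10_p)]
  eL <- peakL$effect[which.max(peakL$minus_log10_p)]
  expect_lt(eC, 0)
  expect_gt(eL, 0)
  # non-target chromosomes are monomorphic and never tested
  expect_true(all(ns$table$cM %in% map$cM[map$chrom == 5]))
})
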