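test_that("the OLS engine matches a normal-equation solve", {
  set.seed(401)
  for (i in 1:5) {
    X <- cbind(intercept = 1, matrix(rnorm(40 * 4), 40,
                                     dimnames = list(NULL, paste0("x", 1:4))))
    y <- rnorm(40)
    f <- fit_linear(y, X)
    expect_equal(unname(f$coefficients), unname(ols_normal_equations(y, X)),
                 tolerance = 1e-8)
  }
  # intercept-only model returns the mean; exact interpolation recovers beta
  y <- rnorm(20)
  f0 <- fit_linear(y, matrix(1, 20, 1, dimnames = list(NULL, "intercept")))
  expect_equal(unname(f0$coefficients), mean(y))
  X <- cbind(intercept = 1, x = 1:20)
  f1 <- fit_linear(3 + 2 * (1:20), X)
  expect_equal(unname(f1$coefficients), c(3, 2), tolerance = 1e-9)
  # rank deficiency is refused with the offending column named
  Xbad <- cbind(intercept = 1, a = 1:20, b = 2 * (1:20))
  expect_error(fit_linear(y, Xbad), "rank deficient.*b")
})

test_that("noiseless data gives perfect recovery of the true term set", {
  model <- effect_model(100, a = c(3, -2, 1, 0, 2),
                        two_way = c("Chr2:Chr4" = 4),
                        three_way = c("Chr1:Chr2:Chr5" = 5),
                        sigma_e = 0)
  set.seed(402)
  tr <- csl_trial(model, reps = 4)
  S3 <- select_threeway(tr$y, tr$geno)
  expect_identical(as.character(S3), "Chr1:Chr2:Chr5")
  S2 <- select_twoway(tr$y, tr$geno, S3)
  expect_setequal(as.character(S2),
                  c("Chr1:Chr2", "Chr1:Chr5", "Chr2:Chr5", "Chr2:Chr4"))
  sel <- final_model(tr$y, tr$geno, S2, S3)
  expect_equal(sel$r2, 1, tolerance = 1e-9)
  # true support plus marginality-protected terms, nothing else
  expect_setequal(sel$terms,
                  c("Chr1", "Chr2", "Chr3", "Chr4", "Chr5",
                    "Chr1:Chr2", "Chr1:Chr5", "Chr2:Chr5", "Chr2:Chr4",
                    "Chr1:Chr2:Chr5"))
  # exact coefficients on the noiseless fit
  est <- setNames(sel$coefficients$estimate, sel$coefficients$term)
  expect_equal(unname(est["Chr1:Chr2:Chr5"]), 5, tolerance = 1e-9)
  expect_equal(unname(est["Chr2:Chr4"]), 4, tolerance = 1e-9)
  expect_equal(unname(est["intercept"]), 100, tolerance = 1e-9)
})

test_that("marginality is enforced in every emitted model", {
  set.seed(403)
  model <- default_effect_model("main_stem_length")
  for (i in 1:10) {
    tr <- csl_trial(model, reps = 8)
    S3 <- select_threeway(tr$y, tr$geno)
    S2 <- select_twoway(tr$y, tr$geno, S3)
    sel <- final_model(tr$y, tr$geno, S2, S3)
    expect_true(isTRUE(check_marginality(sel$terms)))
    if (length(S3))
      expect_true(all(unlist(lapply(S3, nested_terms)) %in% sel$terms))
  }
})

test_that("a selected three-way term forces its two-way shells into the model", {
  model <- effect_model(0, a = rep(0, 5),
                        three_way = c("Chr1:Chr2:Chr5" = 6), sigma_e = 1)
  set.seed(404)
  tr <- csl_trial(model, reps = 12)
  S3 <- select_threeway(tr$y, tr$geno)
  expect_identical(as.character(S3), "Chr1:Chr2:Chr5")
  S2 <- select_twoway(tr$y, tr$geno, S3)
  expect_true(all(c("Chr1:Chr2", "Chr1:Chr5", "Chr2:Chr5") %in% S2))
})

test_that("R2 comparisons are structurally ordered", {
  set.seed(405)
  model <- default_effect_model("main_stem_length")
  tr <- csl_trial(model, reps = 6)
  sel <- epistasis_decomposition(
    data.frame(line_id = rownames(tr$geno), corrected = tr$y), tr$panel)
  expect_gte(sel$r2, sel$r2_main_only)
  # adding any further term to the final model never decreases R2
  X <- design_matrix(tr$geno, 3)
  fit_final <- fit_linear(tr$y, X[, c("intercept", sel$terms), drop = FALSE])
  extra <- setdiff(colnames(X), c("intercept", sel$terms))[1:3]
  for (tm in extra) {
    fit_aug <- fit_linear(tr$y, X[, c("intercept", sel$terms, tm), drop = FALSE])
    expect_gte(fit_aug$r2, fit_final$r2 - 1e-12)
  }
})

test_that("class means reproduce the noiseless cell means with tight CIs", {
  model <- effect_model(10, a = c(1, 2, 0, 0, 3),
                        two_way = c("Chr1:Chr2" = 4), sigma_e = 0)
  set.seed(406)
  tr <- csl_trial(model, reps = 4)
  sel <- final_model(tr$y, tr$geno, S2 = "Chr1:Chr2", S3 = character(0))
  cm <- sel$class_means[["Chr1:Chr2"]]
  expect_equal(nrow(cm), 4L)
  # corner (Col, Col): mu + a1 + a2 + b12 + mean contribution of Chr5 (3/2)
  cc <- cm$mean[cm$class == "Chr1^Col/Chr2^Col"]
  expect_equal(cc, 10 + 1 + 2 + 4 + 1.5, tolerance = 1e-9)
  ll <- cm$mean[cm$class == "Chr1^Ler/Chr2^Ler"]
  expect_equal(ll, 10 + 1.5, tolerance = 1e-9)
})

test_that("single-background sCSL analysis finds the right chromosomes", {
  # only chromosomes 2 and 5 matter; noiseless limit then a null check
  model <- effect_model(50, a = c(0, -4, 0, 0, 6), sigma_e = 0)
  panel <- enumerate_panel(5)
  cls <- classify_panel(panel)
  col_ids <- cls$line_id[cls$background == "Col"]
  sub <- panel[panel$line_id %in% col_ids, ]
  geno <- panel_matrix(sub)[rep(seq_len(nrow(sub)), each = 6), , drop = FALSE]
  y <- unname(genotype_value(sub, model))[rep(seq_len(nrow(sub)), each = 6)]
  res <- scsl_main_effects(y, geno)
  expect_setequal(res$selected, c("Chr2", "Chr5"))
  expect_identical(res$background, "Col")
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  expect_equal(unname(est["Chr5"]), 6, tolerance = 1e-9)
  # mixed backgrounds are rejected
  expect_error(scsl_main_effects(y, panel_matrix(panel)[rep(1:32, 2), ]),
               "multi-substitution")
  both <- panel[panel$line_id %in% cls$line_id[cls$label != "multi_substitution"], ]
  g2 <- panel_matrix(both)[rep(seq_len(nrow(both)), each = 2), , drop = FALSE]
  expect_error(scsl_main_effects(rnorm(nrow(g2)), g2), "mixed backgrounds")
})

test_that("background-interaction model detects chromosome x background effects", {
  set.seed(407)
  # truth: Chr5 effect differs by background (c_5 = 5 sigma)
  sigma <- 1
  model_add <- effect_model(20, a = c(1, -1, 0.5, 0, 2), sigma_e = sigma)
  tr <- scsl_trial(model_add, reps = 12)
  z <- vapply(seq_len(nrow(tr$geno)), function(i) {
    cl <- classify_genotype(tr$geno[i, ])
    as.numeric(cl$background == "Col")
  }, 0)
  x5 <- origin_indicator(tr$geno[, 5])
  y <- tr$y + 5 * sigma * x5 * z
  res <- background_interaction(y, tr$geno)
  expect_identical(res$selected, "Chr5:BG")
  # additive truth: estimated interactions all within their CI of zero
  res0 <- background_interaction(tr$y, tr$geno)
  cf <- res0$coefficients
  ints <- grepl(":BG$", cf$term)
  expect_true(all(cf$ci_lower[ints] <= 0 & cf$ci_upper[ints] >= 0))
  # a missing reciprocal sCSL is reported by name
  keep <- apply(tr$geno, 1, genotype_id) != "CSL_CLLLL"
  expect_error(background_interaction(y[keep], tr$geno[keep, ]),
               "missing reciprocal sCSL: Chr1")
})

test_that("elimination order is deterministic for tied candidates", {
  # exact ties in p-values: symmetric pure-noise-free zero effects
  y <- rep(0, 64)
  geno <- panel_matrix(enumerate_panel(5))[rep(1:32, 2), ]
  y <- y + rep(c(-1, 1), each = 32)  # value independent of genotype
  S3a <- select_threeway(y, geno)
  S3b <- select_threeway(y, geno)
  expect_identical(S3a, S3b)
  expect_length(S3a, 0)
})

test_that("the AIC-style drop rule agrees with the F rule on clear signals", {
  model <- effect_model(10, a = c(4, -4, 0, 0, 3),
                        two_way = c("Chr2:Chr4" = 6), sigma_e = 1)
  set.seed(408)
  tr <- csl_trial(model, reps = 12)
  S3f <- select_threeway(tr$y, tr$geno, criterion = "f")
  S3a <- select_threeway(tr$y, tr$geno, criterion = "aic")
  expect_identical(as.character(S3a), as.character(S3f))
  S2f <- select_twoway(tr$y, tr$geno, S3f, criterion = "f")
  S2a <- select_twoway(tr$y, tr$geno, S3a, criterion = "aic")
  expect_setequal(as.character(S2a), as.character(S2f))
  expect_identical(as.character(S2a), "Chr2:Chr4")
})
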