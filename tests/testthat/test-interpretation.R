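trained_tiny <- function(seed = 30, effects = list(effect_spec(1, "shared")),
                         n = 240, q = 80, r = 6, gpp = 12) {
  sim <- simulate_spin_data(sim_config(n = n, q = q, r = r,
                                       genes_per_pathway = gpp, overlap = 0,
                                       effects = effects, seed = seed))
  sp <- stratified_split(sim$dataset, seed = seed)
  nz <- fit_normalizer(sp$train$expression)
  sets <- lapply(sp[c("train", "validation", "test")],
                 function(d) apply_normalizer(nz, d))
  sets <- lapply(sets, align_dataset, mask = sim$mask)
  cfg <- spin_config("risk", seed = seed, sparsity_grid = 0,
                     max_epochs = 200L)
  fit <- spin_train(spin_model(sim$mask, cfg), sets$train, sets$validation)
  list(model = fit$model, sets = sets, sim = sim, normalizer = nz)
}

test_that("a pathway with zero outgoing weights has zero importance, class none", {
  tt <- trained_tiny(seed = 31)
  m <- tt$model
  m$hidden[[1]]$M[2, ] <- 0   # disconnect pathway 2 from everything downstream
  imp <- global_importance(m, tt$sets$train, level = "pathway", alpha = 0.05)
  row <- imp[imp$feature == m$mask$pathway_ids[2], ]
  expect_equal(row$score_male, 0)
  expect_equal(row$score_female, 0)
  expect_identical(row$class, "none")
})

test_that("importance report satisfies FDR monotonicity and the class rule", {
  tt <- trained_tiny(seed = 32)
  for (level in c("pathway", "gene")) {
    imp <- global_importance(tt$model, tt$sets$train, level = level,
                             alpha = 0.05)
    expect_true(all(imp$q_male >= imp$p_male - 1e-12))
    expect_true(all(imp$q_female >= imp$p_female - 1e-12))
    # adjusted p monotone in raw p within each sex family
    for (sx in c("male", "female")) {
      p <- imp[[paste0("p_", sx)]]; q <- imp[[paste0("q_", sx)]]
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-12))
    }
    sig_m <- imp$q_male < 0.05 & imp$score_male > 0
    sig_f <- imp$q_female < 0.05 & imp$score_female > 0
    want <- ifelse(sig_m & sig_f, "shared",
            ifelse(sig_m, "male_specific",
            ifelse(sig_f, "female_specific", "none")))
    expect_identical(imp$class, want)
  }
})

test_that("symmetric branches give no systematic sex difference in importance", {
  # tie the branches so male- and female-routed computation is identical;
  # paired per-pathway scores should differ only through sampling of rows
  diffs <- sapply(c(33, 34, 35), function(sd) {
    tt <- trained_tiny(seed = sd)
    m <- tt$model
    m$W_G_female <- m$W_G_male; m$b_G_female <- m$b_G_male
    imp <- global_importance(m, tt$sets$train, level = "pathway",
                             alpha = 0.05)
    mean(imp$score_male - imp$score_female)
  })
  pooled <- sapply(c(33, 34, 35), function(sd) {
    tt <- trained_tiny(seed = sd)
    imp <- global_importance(tt$model, tt$sets$train, level = "pathway",
                             alpha = 0.05)
    mean(abs(imp$score_male) + abs(imp$score_female)) / 2
  })
  # the signed gap is small relative to the typical score magnitude
  expect_lt(mean(abs(diffs)), 0.5 * mean(pooled))
})

test_that("type-I control on null data: significant fraction stays near alpha", {
  # untrained models on data with no planted effects: node values are
  # independent of the outcome, so raw p-values are uniform
  set.seed(36)
  alpha <- 0.05
  frac <- replicate(20, {
    sim <- simulate_spin_data(sim_config(n = 160, q = 60, r = 8,
      genes_per_pathway = 7, overlap = 0, effects = list(),
      seed = sample.int(1e6, 1)))
    d <- align_dataset(sim$dataset, sim$mask)
    m <- spin_model(sim$mask, spin_config("risk", seed = sample.int(1e6, 1)))
    imp <- global_importance(m, d, level = "pathway", alpha = alpha)
    mean(imp$class != "none")
  })
  # BH at level alpha over null features: expected discovery fraction is
  # below alpha; allow binomial simulation error
  expect_lt(mean(frac), alpha + 2 * sqrt(alpha * (1 - alpha) / (20 * 8)))
})

test_that("global_importance errors on degenerate outcome groups", {
  tt <- trained_tiny(seed = 37)
  d <- tt$sets$train
  d$label[d$sex == "male"] <- 0   # no male cases
  expect_error(global_importance(tt$model, d), "fewer than 2")
})

test_that("exact Shapley equals the exhaustive-coalition oracle", {
  tt <- trained_tiny(seed = 38)
  bg <- shap_background(tt$model, tt$sets$train, "female", max_rows = 20)
  for (i in 1:3) {
    x <- tt$sets$test$expression[i, , drop = FALSE]
    ex <- shap_explain(tt$model, x, "female", bg)
    expect_identical(ex$method, "exact")
    p_x <- drop(spin_forward(tt$model, x, route_as = "female")$pathway)
    expect_equal(unname(ex$phi), oracle_shapley(tt$model, p_x, bg),
                 tolerance = 1e-10)
    expect_lt(abs(ex$base + sum(ex$phi) - ex$prediction), 1e-6)
  }
  expect_error(shap_explain(tt$model, tt$sets$test$expression[1, , drop = FALSE],
                            "female", bg[0, , drop = FALSE]), "empty")
})

test_that("linear pathway-output map yields w * (p - background mean)", {
  # no hidden nonlinearity active: make the hidden layer an identity-like
  # positive map so the sub-network is affine in the pathway values
  sim <- tiny_sim(seed = 39, n = 60, q = 60, r = 4, gpp = 15)
  m <- spin_model(sim$mask, spin_config("survival", hidden_sizes = 4L,
                                        seed = 39))
  m$hidden[[1]]$W <- diag(4); m$hidden[[1]]$M <- matrix(1, 4, 4)
  m$hidden[[1]]$b <- rep(100, 4)        # keeps every hidden node active
  w <- c(0.5, -1, 2, 0.25)
  m$W_H <- matrix(w)
  d <- align_dataset(sim$dataset, sim$mask)
  bg <- shap_background(m, d, "male", max_rows = 30)
  x <- d$expression[5, , drop = FALSE]
  ex <- shap_explain(m, x, "male", bg)
  p_x <- drop(spin_forward(m, x, route_as = "male")$pathway)
  expect_equal(unname(ex$phi), unname(w * (p_x - colMeans(bg))),
               tolerance = 1e-10)
})

test_that("constant-output model attributes nothing", {
  tt <- trained_tiny(seed = 40)
  m <- tt$model
  m$W_H[] <- 0; m$b_H <- 0.3
  bg <- shap_background(m, tt$sets$train, "male", max_rows = 15)
  ex <- shap_explain(m, tt$sets$test$expression[1, , drop = FALSE], "male", bg)
  expect_true(all(ex$phi == 0))
  expect_equal(ex$base, ex$prediction)
})

test_that("tied branches make counterfactual routing a no-op for attributions", {
  tt <- trained_tiny(seed = 41)
  m <- tt$model
  m$W_G_female <- m$W_G_male; m$b_G_female <- m$b_G_male
  bg <- shap_background(m, tt$sets$train, "male", max_rows = 15)
  x <- tt$sets$test$expression[2, , drop = FALSE]
  e_m <- shap_explain(m, x, "female", bg, route_as = "male")
  e_f <- shap_explain(m, x, "female", bg, route_as = "female")
  expect_equal(e_m$phi, e_f$phi, tolerance = 1e-12)
})

test_that("sampling-mode attributions are additive and track the exact values", {
  tt <- trained_tiny(seed = 42, r = 6)
  bg <- shap_background(tt$model, tt$sets$train, "male", max_rows = 25)
  x <- tt$sets$test$expression[3, , drop = FALSE]
  exact <- shap_explain(tt$model, x, "male", bg)
  sampled <- shap_explain(tt$model, x, "male", bg, exact_limit = 0L,
                          nperm = 64L, seed = 7)
  expect_identical(sampled$method, "sampling")
  expect_lt(abs(sampled$base + sum(sampled$phi) - sampled$prediction), 1e-9)
  expect_equal(unname(sampled$phi), unname(exact$phi), tolerance = 0.02)
})

test_that("waterfall data aggregates the tail and preserves additivity", {
  tt <- trained_tiny(seed = 43)
  bg <- shap_background(tt$model, tt$sets$train, "female", max_rows = 15)
  ex <- shap_explain(tt$model, tt$sets$test$expression[1, , drop = FALSE],
                     "female", bg)
  wf_all <- waterfall_data(ex, top_k = length(ex$phi))
  expect_false("others" %in% wf_all$pathway)
  wf <- waterfall_data(ex, top_k = 2)
  expect_equal(nrow(wf), 3)
  expect_equal(attr(wf, "n_aggregated"), length(ex$phi) - 2L)
  expect_equal(wf$phi[3], sum(ex$phi) - sum(wf$phi[1:2]), tolerance = 1e-12)
  expect_equal(attr(wf, "base") + sum(wf$phi), attr(wf, "prediction"),
               tolerance = 1e-9)
  expect_true(all(diff(abs(wf$phi[1:2])) <= 0))
  expect_error(waterfall_data(ex, top_k = 99), "top_k")
})

test_that("summary data is a per-sample long table with group labels", {
  tt <- trained_tiny(seed = 44)
  bg <- shap_background(tt$model, tt$sets$train, "male", max_rows = 10)
  exps <- lapply(1:5, function(i)
    shap_explain(tt$model, tt$sets$test$expression[i, , drop = FALSE],
                 tt$sets$test$sex[i], bg,
                 sample_id = tt$sets$test$sample_ids[i]))
  groups <- rep(c("Case male", "Control male"), c(3, 2))
  df <- summary_data(exps, groups)
  expect_equal(nrow(df), 5 * length(exps[[1]]$phi))
  # group means recomputed from rows match direct averaging
  g1 <- df[df$group == "Case male" & df$pathway == df$pathway[1], "phi"]
  direct <- mean(sapply(exps[1:3], function(e) e$phi[[df$pathway[1]]]))
  expect_equal(mean(g1), direct, tolerance = 1e-12)
  # empty group is fine, unknown label against a declared set is not
  expect_equal(nrow(summary_data(list(), character(0))), 0)
  expect_error(summary_data(exps, groups, levels = "Case male"),
               "unknown group")
})

test_that("cohort contrast pairs routings and flags planted opposite effects", {
  # constructed model with explicitly opposite branch weights for pathway 1
  sim <- tiny_sim(seed = 45, n = 80, q = 60, r = 4, gpp = 15)
  d <- align_dataset(sim$dataset, sim$mask)
  m <- spin_model(sim$mask, spin_config("risk", hidden_sizes = 4L, seed = 45))
  m$W_G_female <- m$W_G_male
  m$W_G_female[, 1] <- -m$W_G_male[, 1]       # opposite loading on pathway 1
  m$b_G_male[] <- 5; m$b_G_female[] <- 5      # keep ReLU in its linear range
  m$hidden[[1]]$W <- diag(4); m$hidden[[1]]$M <- matrix(1, 4, 4)
  m$hidden[[1]]$b <- rep(50, 4)
  m$W_H <- matrix(c(1, 0.2, 0.2, 0.2))
  # centre the logit so the sigmoid is not saturated under either routing
  m$b_H <- 0
  z_pre <- cbind(
    spin_forward(m, d$expression, route_as = "male")$hidden[[1]] %*% m$W_H,
    spin_forward(m, d$expression, route_as = "female")$hidden[[1]] %*% m$W_H)
  m$b_H <- -mean(z_pre)
  bg_f <- shap_background(m, d, "female", max_rows = 20)
  bg_m <- shap_background(m, d, "male", max_rows = 20)
  females <- which(d$sex == "female")[1:6]
  orig <- lapply(females, function(i)
    shap_explain(m, d$expression[i, , drop = FALSE], "female", bg_f,
                 sample_id = d$sample_ids[i]))
  counter <- lapply(females, function(i)
    shap_explain(m, d$expression[i, , drop = FALSE], "female", bg_m,
                 route_as = "male", sample_id = d$sample_ids[i]))
  cc <- cohort_contrast(orig, counter)
  flips <- attr(cc, "flip_fraction")
  expect_gt(flips[[sim$mask$pathway_ids[1]]], 0.5)
  # paired values align with the single-routing explanations they came from
  expect_equal(cc$phi_original[cc$pathway == sim$mask$pathway_ids[2]],
               sapply(orig, function(e) e$phi[[2]]), tolerance = 1e-12)
  # identical branches: no systematic flips
  m2 <- m; m2$W_G_female <- m2$W_G_male
  bg2 <- shap_background(m2, d, "male", max_rows = 20)
  orig2 <- lapply(females[1:3], function(i)
    shap_explain(m2, d$expression[i, , drop = FALSE], "female", bg2,
                 route_as = "male"))
  cc2 <- cohort_contrast(orig2, orig2)
  expect_true(all(!cc2$sign_flip))
  expect_error(cohort_contrast(orig, counter[1:2]), "equal length")
})
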