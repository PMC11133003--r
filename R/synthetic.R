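#' Planted pathway effect specification
#'
#' @param pathway pathway index (1-based) or id.
#' @param class `"shared"`, `"male_only"`, `"female_only"` or `"opposite"`
#'   (positive in males, negative in females).
#' @param beta effect size on the pathway-score scale. The default 4
#'   corresponds to an odds ratio of about 2.8 per pathway-score standard
#'   deviation with 15-gene pathways — a strongly dysregulated pathway.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(pathway,
                        class = c("shared", "male_only", "female_only",
                                  "opposite"),
                        beta = 4) {
  class <- match.arg(class)
  signs <- switch(class,
                  shared = c(male = 1, female = 1),
                  male_only = c(male = 1, female = 0),
                  female_only = c(male = 0, female = 1),
                  opposite = c(male = 1, female = -1))
  structure(list(pathway = pathway, class = class, beta = beta,
                 beta_male = beta * signs[["male"]],
                 beta_female = beta * signs[["female"]]),
            class = "effect_spec")
}

#' Simulation configuration
#'
#' Defaults describe the package's reference scenario: 600 samples, 500
#' standard-normal genes, 30 pathways of 15 genes with 10% overlap between
#' adjacent pathways (so masks are not orthogonal), balanced sexes, 30%
#' censoring for survival outcomes.
#'
#' @param n,q,r samples, genes, pathways.
#' @param genes_per_pathway pathway size.
#' @param overlap fraction of each pathway's genes shared with the next.
#' @param sex_ratio fraction of male samples.
#' @param task `"risk"` or `"survival"`.
#' @param effects list of [effect_spec()]s; pathways not named are null.
#' @param censoring_rate target fraction censored (survival task).
#' @param baseline_hazard baseline exponential hazard rate.
#' @param label_noise probability of flipping a binary label.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 600L, q = 500L, r = 30L, genes_per_pathway = 15L,
                       overlap = 0.1, sex_ratio = 0.5,
                       task = c("risk", "survival"), effects = list(),
                       censoring_rate = 0.3, baseline_hazard = 0.1,
                       label_noise = 0, seed = 1L) {
  task <- match.arg(task)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("censoring_rate must lie in [0, 1)")
  if (length(effects) > 0 && inherits(effects, "effect_spec"))
    effects <- list(effects)
  structure(list(n = as.integer(n), q = as.integer(q), r = as.integer(r),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 overlap = overlap, sex_ratio = sex_ratio, task = task,
                 effects = effects, censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "sim_config")
}

sim_membership <- function(config) {
  gpp <- config$genes_per_pathway
  shared <- round(config$overlap * gpp)
  stride <- gpp - shared
  starts <- (seq_len(config$r) - 1L) * stride + 1L
  if (max(starts) + gpp - 1L > config$q)
    stopf("q=%d too small for %d pathways of %d genes with overlap %.2f",
          config$q, config$r, gpp, config$overlap)
  lapply(starts, function(s) s:(s + gpp - 1L))
}

resolve_effects <- function(config, pathway_ids) {
  effects <- lapply(config$effects, function(e) {
    if (!inherits(e, "effect_spec")) stopf("effects must be effect_spec objects")
    idx <- if (is.numeric(e$pathway)) as.integer(e$pathway)
           else match(e$pathway, pathway_ids)
    if (is.na(idx) || idx < 1 || idx > length(pathway_ids))
      stopf("planted pathway '%s' outside the pathway universe", e$pathway)
    e$pathway <- pathway_ids[idx]; e$index <- idx
    e
  })
  if (anyDuplicated(vapply(effects, `[[`, integer(1), "index")))
    stopf("a pathway can carry at most one planted effect")
  effects
}

sim_linear_predictor <- function(scores, sex, effects) {
  eta <- numeric(nrow(scores))
  for (e in effects) {
    beta <- ifelse(sex == "male", e$beta_male, e$beta_female)
    eta <- eta + beta * scores[, e$index]
  }
  eta
}

# survival times exponential with rate baseline * exp(eta); independent
# uniform censoring with the upper bound tuned numerically to hit the target
sim_outcome <- function(config, eta, u_label, u_time = NULL) {
  if (config$task == "risk") {
    label <- as.numeric(u_label < stats::plogis(eta))
    if (config$label_noise > 0) {
      flip <- stats::runif(length(label)) < config$label_noise
      label[flip] <- 1 - label[flip]
    }
    list(label = label)
  } else {
    t_event <- stats::qexp(u_time, rate = config$baseline_hazard * exp(eta))
    if (config$censoring_rate > 0) {
      target <- config$censoring_rate
      f <- function(cmax) mean(pmin(t_event / cmax, 1)) - target
      upper <- max(t_event) * 2
      cmax <- stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
      cens <- u_label * cmax
      list(time = pmax(pmin(t_event, cens), 1e-12),
           event = as.numeric(t_event <= cens))
    } else list(time = t_event, event = rep(1, length(t_event)))
  }
}

#' Generate a synthetic dataset with planted pathway effects
#'
#' Expression is i.i.d. standard normal per gene. Each pathway's score is the
#' mean of its member genes; the per-sample linear predictor sums the planted
#' sex-dependent effects `beta_sex * score`. Survival times are exponential
#' with rate proportional to `exp(eta)` under independent uniform censoring
#' tuned to the target rate; binary labels are Bernoulli with probability
#' `sigmoid(eta)` plus optional label flips. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `spin_dataset`), `mask` (a
#'   `pathway_mask`), `effects` (resolved effect specs) and `scores`
#'   (n x r true pathway scores).
#' @export
simulate_spin_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("G%04d", seq_len(config$q))
  pathway_ids <- sprintf("PW%02d", seq_len(config$r))
  members <- sim_membership(config)
  effects <- resolve_effects(config, pathway_ids)
  with_seed(config$seed, {
    X <- matrix(stats::rnorm(config$n * config$q), config$n, config$q,
                dimnames = list(sprintf("S%04d", seq_len(config$n)), gene_ids))
    n_male <- round(config$sex_ratio * config$n)
    sex <- sample(rep(c("male", "female"), c(n_male, config$n - n_male)))
    scores <- vapply(members, function(g) rowMeans(X[, g, drop = FALSE]),
                     numeric(config$n))
    eta <- sim_linear_predictor(scores, sex, effects)
    u_label <- stats::runif(config$n)
    u_time <- if (config$task == "survival") stats::runif(config$n)
    out <- sim_outcome(config, eta, u_label, u_time)
  })
  mask_mat <- matrix(0, config$q, config$r,
                     dimnames = list(gene_ids, pathway_ids))
  for (j in seq_len(config$r)) mask_mat[members[[j]], j] <- 1
  keep <- rowSums(mask_mat) > 0
  mask <- structure(list(matrix = mask_mat[keep, , drop = FALSE],
                         gene_ids = gene_ids[keep],
                         pathway_ids = pathway_ids),
                    class = "pathway_mask")
  dataset <- if (config$task == "risk")
    spin_dataset(X, sex, label = out$label)
  else spin_dataset(X, sex, time = out$time, event = out$event)
  list(dataset = dataset, mask = mask, effects = effects, scores = scores)
}

#' Matched opposite-effect / shared-effect dataset pair
#'
#' Demonstrates the net-canceling phenomenon: one dataset plants a single
#' opposite-direction pathway effect (`beta = +1` in males, `-1` in
#' females), the other the same pathway with a shared `+1` effect. The two
#' datasets share expression, sex labels and random draws, so they differ
#' only in how female outcomes are constructed. In the opposite-effect
#' dataset the sex-pooled association between pathway score and outcome
#' cancels to zero while the within-sex associations are opposite-signed.
#'
#' @param config a [sim_config()]; its `effects` are replaced by the
#'   scenario's single planted pathway.
#' @param pathway index of the planted pathway.
#' @param beta magnitude of the planted effect (default 1).
#' @return list with `opposite` and `shared` generation results (as returned
#'   by [simulate_spin_data()]).
#' @export
opposite_effect_scenario <- function(config = sim_config(), pathway = 1L,
                                     beta = 1) {
  make <- function(class) {
    cfg <- config
    cfg$effects <- list(effect_spec(pathway, class, beta))
    simulate_spin_data(cfg)
  }
  list(opposite = make("opposite"), shared = make("shared"))
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Writes `expression.tsv` (header of gene ids, first column of sample ids),
#' `clinical.tsv` and `pathways.gmt` under `dir`; values use 17 significant
#' digits so a round-trip through [load_dataset()] and [read_gmt()]
#' reproduces them bit-identically.
#'
#' @param dataset a `spin_dataset`.
#' @param mask a `pathway_mask`.
#' @param dir output directory (created if needed).
#' @return named vector of the three file paths.
#' @export
write_fixture <- function(dataset, mask, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             gmt = file.path(dir, "pathways.gmt"))
  expr <- dataset$expression
  df <- data.frame(sample_id = rownames(expr),
                   apply(expr, 2, format_full), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(expr)
  utils::write.table(df, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- data.frame(sample_id = dataset$sample_ids, sex = dataset$sex,
                     stringsAsFactors = FALSE)
  if (dataset$task == "survival") {
    clin$time <- format_full(dataset$time); clin$event <- dataset$event
  } else clin$label <- dataset$label
  utils::write.table(clin, paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- vapply(seq_along(mask$pathway_ids), function(j) {
    genes <- mask$gene_ids[mask$matrix[, j] == 1]
    paste(c(mask$pathway_ids[j], "synthetic", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, paths["gmt"])
  paths
}
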