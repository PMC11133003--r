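# ---- shared internals ----

# forward of the pathway->output sub-network: P (n x r) -> prediction
subnet_forward <- function(model, P) {
  A <- as.matrix(P)
  for (h in model$hidden)
    A <- relu(sweep(A %*% (h$W * h$M), 2, h$b, `+`))
  z <- drop(A %*% model$W_H)
  if (model$config$task == "risk") z <- stats::plogis(z + model$b_H)
  z
}

# per-sample gradients of the model output w.r.t. gene-layer inputs and
# pathway-layer node values (risk task: gradient of the sigmoid risk score)
node_gradients <- function(model, expression, sex, route_as = NULL) {
  trace <- spin_forward(model, expression, sex, route_as)
  n <- nrow(expression)
  routing <- trace$routed_sex
  L <- length(model$hidden)
  H_L <- trace$hidden[[L]]
  dOut <- if (model$config$task == "risk") {
    z_pre <- drop(H_L %*% model$W_H) + model$b_H
    matrix(stats::dlogis(z_pre), ncol = 1)   # sigmoid'(z)
  } else matrix(1, n, 1)
  dA <- dOut %*% t(model$W_H)
  for (l in rev(seq_along(model$hidden))) {
    h <- model$hidden[[l]]
    dpre <- dA * (trace$hidden[[l]] > 0)
    dA <- dpre %*% t(h$W * h$M)
  }
  pathway_grad <- dA                       # n x r, d output / d pathway node
  dPpre <- dA * (trace$pathway > 0)
  gene_grad <- matrix(0, n, ncol(expression))
  for (s in c("male", "female")) {
    rows <- which(routing == s)
    if (length(rows) == 0) next
    Wg <- (if (s == "male") model$W_G_male else model$W_G_female) *
      model$mask$matrix
    gene_grad[rows, ] <- dPpre[rows, , drop = FALSE] %*% t(Wg)
  }
  list(gene = gene_grad, pathway = pathway_grad, trace = trace)
}

rank_test_p <- function(values, group1, group2) {
  v1 <- values[group1]; v2 <- values[group2]
  if (length(unique(c(v1, v2))) < 2) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(v1, v2, exact = FALSE)$p.value)
  if (is.na(p)) 1 else p
}

# ---- global interpretation ----

#' Sex-specific global importance and shared/specific classification
#'
#' For each feature (gene or pathway) and each sex, the importance score is
#' the mean over that sex's samples of `|gradient x node value|` — the
#' absolute first-order contribution of the node to the model output. The
#' significance of a feature within a sex is assessed by a two-sample
#' Wilcoxon rank-sum test between outcome groups within that sex (risk
#' task: case versus control; survival: top versus bottom prognostic-index
#' tertiles), with Benjamini-Hochberg FDR correction within each (level,
#' sex) family. The values tested are label-independent summaries — the
#' expression values at gene level and the annotation-defined pathway
#' enrichment score (mask-normalized mean of member genes) at pathway level
#' — rather than the trained node values: trained first-layer weights fit
#' label noise in the development cohort, so a rank test on trained node
#' values over that cohort is anti-conservative for null features, while
#' the enrichment score is independent of the outcome under the null and
#' keeps the test's false discovery rate at its nominal level. A feature is
#' classified `shared` when its FDR-adjusted p-value is below `alpha` in
#' both sexes, `male_specific` / `female_specific` when in exactly one,
#' else `none`; a feature whose importance score is zero in a sex (e.g. a
#' pathway fully disconnected by pruning) is never called significant in
#' that sex, since it cannot contribute to the prediction.
#'
#' @param model a trained `spin_model`.
#' @param dataset an aligned, normalized `spin_dataset` with both sexes.
#' @param level `"pathway"` or `"gene"`.
#' @param alpha adjusted-p threshold (default `1e-5`).
#' @return a data.frame of class `spin_importance`: one row per feature with
#'   per-sex scores, raw and adjusted p-values, and the class call.
#' @export
global_importance <- function(model, dataset, level = c("pathway", "gene"),
                              alpha = 1e-5) {
  level <- match.arg(level)
  grads <- node_gradients(model, dataset$expression, dataset$sex)
  values <- if (level == "gene") dataset$expression else grads$trace$pathway
  gradient <- if (level == "gene") grads$gene else grads$pathway
  feature_ids <- if (level == "gene") model$mask$gene_ids
                 else model$mask$pathway_ids
  contrib <- abs(gradient * values)
  # label-independent values for the significance test (see above)
  test_values <- if (level == "gene") dataset$expression
  else dataset$expression %*%
    sweep(model$mask$matrix, 2, pmax(colSums(model$mask$matrix), 1), `/`)

  res <- list()
  for (s in c("male", "female")) {
    rows <- which(dataset$sex == s)
    if (length(rows) < 4)
      stopf("sex '%s' has too few samples for outcome groups", s)
    if (dataset$task == "risk") {
      g1 <- rows[dataset$label[rows] == 1]
      g2 <- rows[dataset$label[rows] == 0]
    } else {
      pi_s <- grads$trace$output[rows]
      qs <- stats::quantile(pi_s, c(1 / 3, 2 / 3), type = 7)
      g1 <- rows[pi_s >= qs[2]]   # high-risk tertile
      g2 <- rows[pi_s <= qs[1]]   # low-risk tertile
    }
    if (length(g1) < 2 || length(g2) < 2)
      stopf("sex '%s' has fewer than 2 samples in an outcome group", s)
    score <- colMeans(contrib[rows, , drop = FALSE])
    p <- vapply(seq_along(feature_ids), function(j)
      rank_test_p(test_values[, j], g1, g2), numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    res[[s]] <- list(score = score, p = p, q = q,
                     sig = q < alpha & score > 0)
  }
  class_call <- ifelse(res$male$sig & res$female$sig, "shared",
                ifelse(res$male$sig, "male_specific",
                ifelse(res$female$sig, "female_specific", "none")))
  out <- data.frame(feature = feature_ids, level = level,
                    score_male = res$male$score,
                    score_female = res$female$score,
                    p_male = res$male$p, p_female = res$female$p,
                    q_male = res$male$q, q_female = res$female$q,
                    class = class_call,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  class(out) <- c("spin_importance", "data.frame")
  out
}

# ---- local (Shapley) interpretation ----

#' Background pathway activations for Shapley explanations
#'
#' Routes reference samples (typically the training set) through the branch
#' named by `sex` and returns their pathway-layer activations, subsampled to
#' at most `max_rows` rows with a fixed seed.
#'
#' @param model a `spin_model`.
#' @param dataset reference `spin_dataset`.
#' @param sex branch to route through (`"male"` or `"female"`).
#' @param max_rows background cap.
#' @param seed subsampling seed.
#' @return matrix of pathway activations (rows x pathways).
#' @export
shap_background <- function(model, dataset, sex, max_rows = 200L, seed = 1L) {
  P <- spin_forward(model, dataset$expression, route_as = sex)$pathway
  if (nrow(P) > max_rows)
    P <- with_seed(seed, P[sample(nrow(P), max_rows), , drop = FALSE])
  P
}

coalition_values <- function(model, p_x, background, subsets_bits) {
  # subsets_bits: logical matrix (#coalitions x r); value of a coalition is
  # the mean sub-network output with coalition features at the sample's
  # pathway activations and the rest at background values
  n_bg <- nrow(background)
  n_c <- nrow(subsets_bits)
  v <- numeric(n_c)
  chunk <- max(1L, floor(2e6 / n_bg))
  for (start in seq(1L, n_c, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_c)
    big <- background[rep(seq_len(n_bg), times = length(idx)), , drop = FALSE]
    onoff <- subsets_bits[rep(idx, each = n_bg), , drop = FALSE]
    big[onoff] <- matrix(p_x, nrow(big), length(p_x), byrow = TRUE)[onoff]
    preds <- subnet_forward(model, big)
    v[idx] <- colMeans(matrix(preds, n_bg))
  }
  v
}

shapley_exact <- function(model, p_x, background) {
  r <- length(p_x)
  ints <- 0:(2^r - 1)
  bits <- matrix(FALSE, length(ints), r)
  for (j in seq_len(r)) bits[, j] <- bitwAnd(ints, 2^(j - 1)) > 0
  v <- coalition_values(model, p_x, background, bits)
  sizes <- rowSums(bits)
  lw <- lgamma(0:(r - 1) + 1) + lgamma(r - (0:(r - 1))) - lgamma(r + 1)
  w <- exp(lw)                       # |S|! (r-|S|-1)! / r!
  phi <- numeric(r)
  for (j in seq_len(r)) {
    without <- which(!bits[, j])
    phi[j] <- sum(w[sizes[without] + 1] *
                    (v[without + 2^(j - 1)] - v[without]))
  }
  phi
}

shapley_sampling <- function(model, p_x, background, nperm, seed) {
  r <- length(p_x)
  perms <- with_seed(seed, replicate(nperm, sample.int(r), simplify = FALSE))
  # antithetic pairs: each permutation together with its reverse
  perms <- c(perms, lapply(perms, rev))
  phi <- numeric(r)
  for (perm in perms) {
    bits <- matrix(FALSE, r + 1, r)
    for (k in seq_len(r)) bits[k + 1, ] <- bits[k, ]
    for (k in seq_len(r)) bits[(k + 1):(r + 1), perm[k]] <- TRUE
    v <- coalition_values(model, p_x, background, bits)
    phi[perm] <- phi[perm] + (v[-1] - v[-(r + 1)])
  }
  phi / length(perms)
}

#' Shapley-value local explanation of one sample
#'
#' Attributes the deviation of the sample's prediction from a base value
#' (the mean prediction over the background) across the pathway-layer nodes
#' of the pathway-to-output sub-network. Exact Shapley enumeration is used
#' when the number of pathways `r <= exact_limit` (default 15); otherwise an
#' antithetic permutation-sampling approximation whose residual is
#' redistributed proportionally to `|phi|` so that additivity
#' `base + sum(phi) = prediction` holds exactly. `route_as` reroutes the
#' sample's expression through the other sex's pathway weights before
#' explaining — the cross-sex counterfactual.
#'
#' @param model a trained `spin_model`.
#' @param x a single expression row (length q, aligned to the model).
#' @param sex the sample's sex.
#' @param background pathway-activation matrix from [shap_background()]
#'   (reference samples routed through the same branch as the explanation).
#' @param route_as optional counterfactual branch.
#' @param sample_id identifier recorded in the explanation.
#' @param exact_limit largest `r` for exhaustive coalition enumeration.
#' @param nperm sampled permutations (doubled by antithetics) above the
#'   exact limit.
#' @param seed sampling seed.
#' @return an object of class `spin_explanation`: per-pathway attributions
#'   `phi`, `base`, `prediction`, node values, enrichment direction
#'   (node value above/below the background mean), sex and routed sex.
#' @export
shap_explain <- function(model, x, sex, background, route_as = NULL,
                         sample_id = NA_character_, exact_limit = 15L,
                         nperm = 32L, seed = 1L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(background) == 0) stopf("empty background")
  routed <- route_as %||% check_sex(sex)
  p_x <- drop(spin_forward(model, x, route_as = routed)$pathway)
  r <- length(p_x)
  prediction <- unname(subnet_forward(model, matrix(p_x, 1)))
  base <- mean(subnet_forward(model, background))
  exact <- r <= exact_limit
  phi <- if (exact) shapley_exact(model, p_x, background)
         else shapley_sampling(model, p_x, background, nperm, seed)
  if (!exact) {
    resid <- (prediction - base) - sum(phi)
    tot <- sum(abs(phi))
    phi <- phi + if (tot > 0) resid * abs(phi) / tot else resid / r
  }
  names(phi) <- model$mask$pathway_ids
  bg_mean <- colMeans(background)
  structure(list(sample_id = sample_id, sex = if (is.null(sex)) routed else sex,
                 routed_sex = routed, phi = phi, base = base,
                 prediction = prediction,
                 node_values = stats::setNames(p_x, model$mask$pathway_ids),
                 enrichment = ifelse(p_x >= bg_mean, "up", "down"),
                 method = if (exact) "exact" else "sampling"),
            class = "spin_explanation")
}

#' @export
print.spin_explanation <- function(x, ...) {
  cat(sprintf(
    "spin_explanation [%s]: sample %s routed as %s; f(x)=%.4f, base=%.4f\n",
    x$method, x$sample_id, x$routed_sex, x$prediction, x$base))
  top <- utils::head(x$phi[order(-abs(x$phi))], 5)
  for (nm in names(top))
    cat(sprintf("  %-24s phi=%+.5f (%s)\n", nm, top[[nm]],
                x$enrichment[match(nm, names(x$phi))]))
  invisible(x)
}

#' Waterfall-plot data for a local explanation
#'
#' Orders pathways by absolute attribution (descending) and aggregates
#' entries beyond `top_k` into a single remainder term, so that
#' `base + listed terms + others = prediction`.
#'
#' @param explanation a `spin_explanation`.
#' @param top_k number of pathways listed individually.
#' @return data.frame with columns `pathway`, `phi`, `enrichment`
#'   (remainder row `pathway = "others"`), with `base` and `prediction`
#'   attributes.
#' @export
waterfall_data <- function(explanation, top_k = 15L) {
  phi <- explanation$phi
  if (top_k > length(phi)) stopf("top_k exceeds the number of pathways")
  ord <- order(-abs(phi), seq_along(phi))
  top <- ord[seq_len(top_k)]
  df <- data.frame(pathway = names(phi)[top], phi = unname(phi[top]),
                   enrichment = explanation$enrichment[top],
                   stringsAsFactors = FALSE)
  if (top_k < length(phi)) {
    rest <- ord[-seq_len(top_k)]
    df <- rbind(df, data.frame(pathway = "others", phi = sum(phi[rest]),
                               enrichment = NA_character_))
  }
  attr(df, "base") <- explanation$base
  attr(df, "prediction") <- explanation$prediction
  attr(df, "n_aggregated") <- max(length(phi) - top_k, 0L)
  df
}

#' Summary-plot data over a collection of explanations
#'
#' Long table of one row per (explanation, pathway) pair with the subgroup
#' label, attribution and node value — beeswarm-ready, with no per-sample
#' aggregation.
#'
#' @param explanations list of `spin_explanation`s.
#' @param groups subgroup label per explanation (e.g. "Asthma female").
#' @param levels optional set of admissible group labels; labels outside it
#'   raise an error.
#' @return data.frame with columns `group`, `pathway`, `sample_id`, `phi`,
#'   `node_value`.
#' @export
summary_data <- function(explanations, groups, levels = NULL) {
  if (length(explanations) != length(groups))
    stopf("one group label per explanation required")
  if (length(explanations) == 0)
    return(data.frame(group = character(0), pathway = character(0),
                      sample_id = character(0), phi = numeric(0),
                      node_value = numeric(0), stringsAsFactors = FALSE))
  if (!is.null(levels)) {
    bad <- setdiff(unique(groups), levels)
    if (length(bad) > 0)
      stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  }
  rows <- lapply(seq_along(explanations), function(i) {
    e <- explanations[[i]]
    data.frame(group = groups[[i]], pathway = names(e$phi),
               sample_id = e$sample_id, phi = unname(e$phi),
               node_value = unname(e$node_values),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Paired original/counterfactual attribution contrast
#'
#' Pairs each sample's attributions under its own sex's routing with the
#' attributions of the same expression profile routed through the opposite
#' branch, and flags pathways whose attribution direction flips between the
#' two routings.
#'
#' @param original list of `spin_explanation`s under natural routing.
#' @param counterfactual matching list under the opposite routing (same
#'   samples, same pathway ordering).
#' @return data.frame with one row per (sample, pathway): `phi_original`,
#'   `phi_counterfactual` and logical `sign_flip`; per-pathway flip
#'   fractions in attribute `flip_fraction`.
#' @export
cohort_contrast <- function(original, counterfactual) {
  if (length(original) != length(counterfactual))
    stopf("explanation lists must have equal length")
  rows <- lapply(seq_along(original), function(i) {
    a <- original[[i]]; b <- counterfactual[[i]]
    if (!identical(names(a$phi), names(b$phi)))
      stopf("pathway ordering mismatch between paired explanations")
    data.frame(sample_id = a$sample_id, pathway = names(a$phi),
               routed_original = a$routed_sex,
               phi_original = unname(a$phi),
               phi_counterfactual = unname(b$phi),
               sign_flip = unname(a$phi * b$phi < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "flip_fraction") <-
    tapply(out$sign_flip, out$pathway, mean)[unique(out$pathway)]
  out
}
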