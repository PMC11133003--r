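#' Stratified train/validation/test split
#'
#' Splits samples into development (default 80%) and test (20%) sets with
#' stratified random sampling, then splits development into training (80% of
#' development) and validation. Survival datasets stratify on sex; binary
#' datasets stratify on sex x disease status jointly. Deterministic given the
#' seed.
#'
#' @param dataset a `spin_dataset`.
#' @param dev_fraction fraction of each stratum assigned to development.
#' @param train_fraction_of_dev fraction of development assigned to training.
#' @param seed integer seed.
#' @return list of `spin_dataset`s: `train`, `validation`, `test`, plus
#'   `indices` (the index vectors into the original dataset).
#' @export
stratified_split <- function(dataset, dev_fraction = 0.8,
                             train_fraction_of_dev = 0.8, seed = 1L) {
  if (dev_fraction <= 0 || dev_fraction >= 1 ||
      train_fraction_of_dev <= 0 || train_fraction_of_dev >= 1)
    stopf("split fractions must lie strictly in (0, 1)")
  strata <- if (dataset$task == "risk")
    paste(dataset$sex, dataset$label, sep = ".") else dataset$sex
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (s in sort(unique(strata))) {
      members <- which(strata == s)
      n_s <- length(members)
      n_test <- round((1 - dev_fraction) * n_s)
      n_dev <- n_s - n_test
      n_val <- round((1 - train_fraction_of_dev) * n_dev)
      n_train <- n_dev - n_val
      if (min(n_test, n_val, n_train) < 1)
        stopf("stratum '%s' (n=%d) too small to appear in all partitions",
              s, n_s)
      perm <- sample(members)
      idx$test <- c(idx$test, perm[seq_len(n_test)])
      idx$validation <- c(idx$validation, perm[n_test + seq_len(n_val)])
      idx$train <- c(idx$train, perm[n_test + n_val + seq_len(n_train)])
    }
  })
  idx <- lapply(idx, sort)
  list(train = subset_samples(dataset, idx$train),
       validation = subset_samples(dataset, idx$validation),
       test = subset_samples(dataset, idx$test),
       indices = idx)
}

#' Fit a train-set normalizer
#'
#' Per-gene mean and population standard deviation estimated on training rows
#' only; genes with zero variance are dropped with a warning. Validation and
#' test sets must be transformed with these training statistics.
#'
#' @param expression training expression matrix (samples x genes).
#' @return an object of class `spin_normalizer`.
#' @export
fit_normalizer <- function(expression) {
  expression <- as.matrix(expression)
  mu <- colMeans(expression)
  sdev <- sqrt(colMeans(sweep(expression, 2, mu)^2))
  keep <- sdev > 1e-12
  if (!all(keep))
    warning(sprintf("dropping %d constant gene(s): %s", sum(!keep),
                    paste(colnames(expression)[!keep], collapse = ", ")),
            call. = FALSE)
  structure(list(mean = mu[keep], sd = sdev[keep],
                 genes = colnames(expression)[keep]),
            class = "spin_normalizer")
}

#' Apply a fitted normalizer
#'
#' Standardizes columns with the training mean/sd; drops genes the fit
#' removed. Re-applying to already-standardized output is an error (the
#' statistics would be wrong the second time).
#'
#' @param normalizer a `spin_normalizer` from [fit_normalizer()].
#' @param x expression matrix or `spin_dataset` to transform.
#' @return the standardized matrix or dataset, tagged with attribute
#'   `spin_standardized`.
#' @export
apply_normalizer <- function(normalizer, x) {
  if (!inherits(normalizer, "spin_normalizer"))
    stopf("apply_normalizer called with an unfitted normalizer")
  if (inherits(x, "spin_dataset")) {
    x$expression <- apply_normalizer(normalizer, x$expression)
    x$gene_ids <- colnames(x$expression)
    return(x)
  }
  if (isTRUE(attr(x, "spin_standardized")))
    stopf("expression is already standardized; refusing to normalize twice")
  x <- as.matrix(x)[, normalizer$genes, drop = FALSE]
  x <- sweep(sweep(x, 2, normalizer$mean), 2, normalizer$sd, `/`)
  attr(x, "spin_standardized") <- TRUE
  x
}

#' Average negative log Cox partial likelihood
#'
#' `-(1/d) * sum over events of (z_i - log sum_{t_j >= t_i} exp(z_j))` with
#' Breslow handling of tied event times (`d` = number of events). This is the
#' survival-task training loss applied to the network's prognostic index.
#'
#' @param z length-n prognostic indices.
#' @param time,event survival outcome.
#' @return nonnegative scalar loss.
#' @export
cox_loss <- function(z, time, event) {
  d <- sum(event)
  if (d < 1) stopf("cox_loss requires at least one event")
  ord <- order(time)            # ascending; risk set = this and later times
  z_o <- z[ord]; t_o <- time[ord]; e_o <- event[ord]
  m <- max(z_o)
  # reverse cumulative sum of exp(z); ties share the full risk set (Breslow)
  rev_cum <- rev(cumsum(rev(exp(z_o - m))))
  first_at_time <- match(t_o, t_o)   # index of first sample with each time
  logS <- log(rev_cum[first_at_time]) + m
  -(1 / d) * sum((z_o - logS)[e_o == 1])
}

#' Gradient of the Cox partial-likelihood loss
#'
#' Analytic gradient of [cox_loss()] with respect to the prognostic index.
#'
#' @inheritParams cox_loss
#' @return length-n gradient vector (same order as `z`).
#' @export
cox_loss_grad <- function(z, time, event) {
  d <- sum(event)
  if (d < 1) stopf("cox_loss requires at least one event")
  ord <- order(time)
  z_o <- z[ord]; t_o <- time[ord]; e_o <- event[ord]
  m <- max(z_o)
  ez <- exp(z_o - m)
  rev_cum <- rev(cumsum(rev(ez)))
  first_at_time <- match(t_o, t_o)
  S <- rev_cum[first_at_time]        # risk-set sums (scaled by exp(-m))
  # for sample k: sum over events i with t_i <= t_k of 1/S_i
  inv_S_event <- ifelse(e_o == 1, 1 / S, 0)
  cum_inv <- cumsum(inv_S_event)
  last_at_time <- length(t_o) + 1L - match(t_o, rev(t_o))
  g_o <- -(1 / d) * (e_o - ez * cum_inv[last_at_time])
  g <- numeric(length(z)); g[ord] <- g_o
  g
}

#' Mean binary cross-entropy
#'
#' Risk scores at exactly 0 or 1 are clamped to `eps` / `1 - eps` with a
#' warning before taking logs.
#'
#' @param risk length-n predicted risks in (0, 1).
#' @param label length-n 0/1 labels.
#' @param eps clamp width.
#' @return nonnegative scalar loss.
#' @export
bce_loss <- function(risk, label, eps = 1e-12) {
  if (any(risk <= 0 | risk >= 1)) {
    warning("risk scores at 0/1 clamped for the cross-entropy", call. = FALSE)
    risk <- pmin(pmax(risk, eps), 1 - eps)
  }
  -mean(label * log(risk) + (1 - label) * log(1 - risk))
}

# ---- parameter plumbing ----

trainable_names <- function(model) {
  nm <- c("b_G_male", "b_G_female", "W_H",
          if (model$config$task == "risk") "b_H")
  nm <- c("W_G_male", if (model$config$sex_specific) "W_G_female", nm)
  c(nm, unlist(lapply(seq_along(model$hidden), function(l)
    paste0("hidden", l, ".", c("W", "b")))))
}

get_param <- function(model, name) {
  if (grepl("^hidden", name)) {
    parts <- strsplit(sub("hidden", "", name), ".", fixed = TRUE)[[1]]
    model$hidden[[as.integer(parts[1])]][[parts[2]]]
  } else model[[name]]
}

set_param <- function(model, name, value) {
  if (grepl("^hidden", name)) {
    parts <- strsplit(sub("hidden", "", name), ".", fixed = TRUE)[[1]]
    model$hidden[[as.integer(parts[1])]][[parts[2]]] <- value
  } else model[[name]] <- value
  model
}

# forward pass keeping what backprop needs, then gradients of the loss
# w.r.t. every trainable parameter. dz is dLoss/d(pre-head output).
spin_backprop <- function(model, X, routing, dz) {
  n <- nrow(X)
  r <- length(model$mask$pathway_ids)
  P <- matrix(0, n, r)
  for (s in c("male", "female")) {
    rows <- which(routing == s)
    if (length(rows) == 0) next
    Wg <- (if (s == "male") model$W_G_male else model$W_G_female) *
      model$mask$matrix
    bg <- if (s == "male") model$b_G_male else model$b_G_female
    P[rows, ] <- relu(sweep(X[rows, , drop = FALSE] %*% Wg, 2, bg, `+`))
  }
  acts <- list(P)
  A <- P
  for (l in seq_along(model$hidden)) {
    h <- model$hidden[[l]]
    A <- relu(sweep(A %*% (h$W * h$M), 2, h$b, `+`))
    acts[[l + 1]] <- A
  }
  grads <- list()
  dz <- matrix(dz, ncol = 1)
  grads$W_H <- crossprod(A, dz)
  if (model$config$task == "risk") grads$b_H <- sum(dz)
  dA <- dz %*% t(model$W_H)
  for (l in rev(seq_along(model$hidden))) {
    h <- model$hidden[[l]]
    dpre <- dA * (acts[[l + 1]] > 0)
    grads[[paste0("hidden", l, ".W")]] <-
      crossprod(acts[[l]], dpre) * h$M
    grads[[paste0("hidden", l, ".b")]] <- colSums(dpre)
    dA <- dpre %*% t(h$W * h$M)
  }
  dP <- dA * (P > 0)
  if (model$config$sex_specific) {
    for (s in c("male", "female")) {
      rows <- which(routing == s)
      wg <- paste0("W_G_", s); bg <- paste0("b_G_", s)
      if (length(rows) == 0) {
        grads[[wg]] <- model$mask$matrix * 0
        grads[[bg]] <- rep(0, r)
      } else {
        grads[[wg]] <- crossprod(X[rows, , drop = FALSE],
                                 dP[rows, , drop = FALSE]) * model$mask$matrix
        grads[[bg]] <- colSums(dP[rows, , drop = FALSE])
      }
    }
  } else {
    grads$W_G_male <- crossprod(X, dP) * model$mask$matrix
    grads$b_G_male <- colSums(dP)
    grads$b_G_female <- rep(0, r)
  }
  grads
}

model_loss <- function(model, dataset) {
  out <- spin_forward(model, dataset$expression, dataset$sex)$output
  if (model$config$task == "survival")
    cox_loss(out, dataset$time, dataset$event)
  else bce_loss(pmin(pmax(out, 1e-12), 1 - 1e-12), dataset$label)
}

# dLoss/d(pre-head output): for risk the BCE+sigmoid composite gradient
head_grad <- function(model, dataset, output) {
  if (model$config$task == "survival")
    cox_loss_grad(output, dataset$time, dataset$event)
  else (output - dataset$label) / length(dataset$label)
}

run_adam <- function(model, train, validation, epochs, lr, l2, patience) {
  names_tr <- trainable_names(model)
  state <- lapply(names_tr, function(nm) {
    p <- get_param(model, nm); list(m = p * 0, v = p * 0)
  })
  names(state) <- names_tr
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  routing <- if (model$config$sex_specific) check_sex(train$sex)
             else rep("male", length(train$sex))
  best <- list(model = model, val = model_loss(model, validation), epoch = 0L)
  train_losses <- numeric(0); val_losses <- numeric(0)
  t_step <- 0L
  for (epoch in seq_len(epochs)) {
    out <- spin_forward(model, train$expression, train$sex)$output
    loss <- if (model$config$task == "survival")
      cox_loss(out, train$time, train$event)
    else bce_loss(pmin(pmax(out, 1e-12), 1 - 1e-12), train$label)
    if (!is.finite(loss))
      stopf("non-finite training loss at epoch %d; lower the learning rate",
            epoch)
    dz <- head_grad(model, train, out)
    grads <- spin_backprop(model, train$expression, routing, dz)
    t_step <- t_step + 1L
    for (nm in names_tr) {
      g <- grads[[nm]]
      p <- get_param(model, nm)
      if (grepl("^W", nm) || grepl("\\.W$", nm)) g <- g + l2 * p
      st <- state[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[nm]] <- st
      mhat <- st$m / (1 - beta1^t_step)
      vhat <- st$v / (1 - beta2^t_step)
      model <- set_param(model, nm, p - lr * mhat / (sqrt(vhat) + eps))
    }
    if (!model$config$sex_specific) {
      model$W_G_female <- model$W_G_male
      model$b_G_female <- model$b_G_male
    }
    val <- model_loss(model, validation)
    train_losses <- c(train_losses, loss); val_losses <- c(val_losses, val)
    if (val < best$val - 1e-9)
      best <- list(model = model, val = val, epoch = epoch)
    if (epoch - best$epoch >= patience) break
  }
  list(model = best$model, train_loss = train_losses, val_loss = val_losses,
       best_epoch = best$epoch, best_val = best$val)
}

#' Train a spin_model
#'
#' Full-batch Adam on the Cox partial-likelihood loss (survival) or binary
#' cross-entropy (risk), with early stopping on validation loss and the
#' best-validation parameters retained. When the configuration asks for
#' several restarts, additional models are re-initialized from seeds derived
#' from the configuration seed and the restart with the lowest validation
#' loss is kept. When the `sparsity_grid` contains nonzero fractions, the
#' hidden-layer masks are then sparsified by validation-selected magnitude
#' pruning ([sparse_code_masks()]) and briefly fine-tuned. Deterministic
#' given the configuration seed.
#'
#' @param model a `spin_model` whose task matches the datasets' outcome
#'   (used as restart 1; further restarts are rebuilt from its mask and
#'   configuration).
#' @param train,validation aligned, normalized `spin_dataset`s.
#' @param learning_rate,max_epochs,patience,l2 optional overrides of the
#'   configuration values.
#' @return list with `model` (trained) and `report` (class `spin_report`):
#'   per-epoch train/validation losses of the selected restart, best epoch,
#'   chosen sparsity, final validation loss, seed.
#' @export
spin_train <- function(model, train, validation,
                       learning_rate = NULL, max_epochs = NULL,
                       patience = NULL, l2 = NULL) {
  cfg <- model$config
  if (cfg$task != train$task)
    stopf("model task '%s' does not match dataset outcome '%s'",
          cfg$task, train$task)
  lr <- learning_rate %||% cfg$learning_rate
  epochs <- max_epochs %||% cfg$max_epochs
  pat <- patience %||% cfg$patience
  l2 <- l2 %||% cfg$l2
  fit <- run_adam(model, train, validation, epochs, lr, l2, pat)
  n_restarts <- cfg$n_restarts %||% 1L
  if (n_restarts > 1) {
    for (k in 2:n_restarts) {
      cfg_k <- cfg
      cfg_k$seed <- (cfg$seed %% 20000000L) * 100L + k   # keep below 2^31
      fit_k <- run_adam(spin_model(model$mask, cfg_k), train, validation,
                        epochs, lr, l2, pat)
      if (fit_k$best_val < fit$best_val) fit <- fit_k
    }
  }
  model <- fit$model
  chosen_rho <- NULL
  if (any(model$config$sparsity_grid > 0)) {
    pruned <- sparse_code_masks(model, validation, model$config$sparsity_grid)
    model <- pruned$model
    chosen_rho <- pruned$chosen_rho
    if (any(unlist(chosen_rho) > 0) && cfg$finetune_epochs > 0) {
      ft <- run_adam(model, train, validation, cfg$finetune_epochs,
                     lr, l2, pat)
      if (ft$best_val <= fit$best_val) model <- ft$model
      fit$train_loss <- c(fit$train_loss, ft$train_loss)
      fit$val_loss <- c(fit$val_loss, ft$val_loss)
    }
  }
  report <- structure(list(train_loss = fit$train_loss,
                           val_loss = fit$val_loss,
                           best_epoch = fit$best_epoch,
                           chosen_sparsity = chosen_rho,
                           final_val_loss = model_loss(model, validation),
                           seed = cfg$seed),
                      class = "spin_report")
  list(model = model, report = report)
}

#' @export
print.spin_report <- function(x, ...) {
  cat(sprintf("spin_report: %d epochs, best epoch %d, final val loss %.4f%s\n",
              length(x$train_loss), x$best_epoch, x$final_val_loss,
              if (is.null(x$chosen_sparsity)) "" else
                sprintf(", sparsity [%s]",
                        paste(unlist(x$chosen_sparsity), collapse = ", "))))
  invisible(x)
}

#' Sparsify hidden-layer masks by validation-selected magnitude pruning
#'
#' For each hidden layer in turn and each candidate fraction `rho` in the
#' grid, zeroes the `floor(rho * #entries)` smallest-magnitude effective
#' weights (`|W * M|`, ties broken by row then column index) and keeps the
#' `rho` minimizing validation loss (ties toward the larger `rho`). The
#' gene-pathway mask is fixed by annotation and never pruned; hidden masks
#' remain shared across both sex branches.
#'
#' @param model a `spin_model`.
#' @param validation a `spin_dataset` for selection.
#' @param sparsity_grid candidate fractions in `[0, 1]`.
#' @return list with `model` (updated masks), `chosen_rho` (per layer) and
#'   `losses` (per layer, per grid point).
#' @export
sparse_code_masks <- function(model, validation, sparsity_grid) {
  if (length(sparsity_grid) == 0) stopf("empty sparsity grid")
  if (any(sparsity_grid < 0 | sparsity_grid > 1))
    stopf("sparsity fractions must lie in [0, 1]")
  grid <- sort(unique(sparsity_grid))
  chosen <- numeric(length(model$hidden))
  losses <- vector("list", length(model$hidden))
  for (l in seq_along(model$hidden)) {
    layer_losses <- numeric(length(grid))
    candidates <- vector("list", length(grid))
    for (k in seq_along(grid)) {
      cand <- model
      cand$hidden[[l]]$M <- prune_mask(model$hidden[[l]]$W,
                                       model$hidden[[l]]$M, grid[k])
      candidates[[k]] <- cand$hidden[[l]]$M
      layer_losses[k] <- model_loss(cand, validation)
    }
    # minimum loss, ties toward the larger fraction
    best_k <- max(which(layer_losses <= min(layer_losses) + 1e-12))
    model$hidden[[l]]$M <- candidates[[best_k]]
    chosen[l] <- grid[best_k]
    losses[[l]] <- stats::setNames(layer_losses, grid)
  }
  list(model = model, chosen_rho = chosen, losses = losses)
}

# zero the floor(rho * length(W)) smallest-|W*M| entries; stable tie-break
# by (row, column) index
prune_mask <- function(W, M, rho) {
  k <- floor(rho * length(W))
  newM <- matrix(1, nrow(W), ncol(W))
  if (k >= 1) {
    eff <- abs(W * M)
    rows <- row(W); cols <- col(W)
    ord <- order(eff, rows, cols)
    newM[ord[seq_len(k)]] <- 0
  }
  newM
}
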