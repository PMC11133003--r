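# fixture builders and independent oracles shared across test files

tiny_sim <- function(seed = 1, n = 120, q = 80, r = 6, gpp = 12,
                     task = "risk", effects = list(effect_spec(1, "shared"))) {
  simulate_spin_data(sim_config(n = n, q = q, r = r, genes_per_pathway = gpp,
                                task = task, effects = effects, seed = seed))
}

tiny_model <- function(sim, task = "risk", seed = 1, ...) {
  spin_model(sim$mask, spin_config(task, seed = seed, ...))
}

write_tmp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# O(n^2) pair-enumeration oracle for Harrell's C
oracle_cindex <- function(pred, time, event) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  num / den
}

# pairwise-comparison oracle for the AUC
oracle_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  num <- 0
  for (a in pos) for (b in neg)
    num <- num + (a > b) + 0.5 * (a == b)
  num / (length(pos) * length(neg))
}

# explicit risk-set enumeration oracle for the Cox loss
oracle_cox_loss <- function(z, time, event) {
  d <- sum(event)
  tot <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    tot <- tot + z[i] - log(sum(exp(z[risk])))
  }
  -tot / d
}

# exhaustive-coalition Shapley oracle over the pathway->output sub-network
oracle_shapley <- function(model, p_x, background) {
  f_sub <- function(P) spinr:::subnet_forward(model, P)
  r <- length(p_x)
  v <- function(S) {
    Z <- background
    for (j in S) Z[, j] <- p_x[j]
    mean(f_sub(Z))
  }
  vapply(seq_len(r), function(i) {
    others <- setdiff(seq_len(r), i)
    tot <- 0
    for (k in 0:(r - 1)) {
      combs <- if (k == 0) list(integer(0))
               else utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(r - k - 1) / factorial(r)
      for (S in combs) tot <- tot + w * (v(c(S, i)) - v(S))
    }
    tot
  }, numeric(1))
}

# all permutations of 1..n (tiny n only), for exhaustive minimizer checks
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1))
    for (k in 0:(n - 1))
      out[[length(out) + 1]] <- append(p, n, after = k)
  out
}
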