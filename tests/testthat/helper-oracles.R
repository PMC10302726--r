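# Independent oracles used to verify the pipeline's statistical engines.
# These are written from first principles (loops over definitions), never
# calling the code paths they check.

# Newton-Raphson maximizer of the Efron-approximation Cox partial
# likelihood. X: n x p covariate matrix; no ties assumed handled exactly
# (Efron weights used when ties occur).
oracle_cox_efron <- function(X, time, event, tol = 1e-12, maxit = 100) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      d <- length(D)
      sR <- sum(w[R]); sD <- sum(w[D])
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
    }
    ll
  }
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    grad <- rep(0, p)
    hess <- matrix(0, p, p)
    for (t in sort(unique(time[event == 1]))) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      d <- length(D)
      sR <- sum(w[R]); sD <- sum(w[D])
      xR <- colSums(X[R, , drop = FALSE] * w[R])
      xD <- colSums(X[D, , drop = FALSE] * w[D])
      xxR <- crossprod(X[R, , drop = FALSE] * sqrt(w[R]))
      xxD <- crossprod(X[D, , drop = FALSE] * sqrt(w[D]))
      grad <- grad + colSums(X[D, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        psi <- sR - (l / d) * sD
        z1 <- xR - (l / d) * xD
        z2 <- xxR - (l / d) * xxD
        grad <- grad - z1 / psi
        hess <- hess + z2 / psi - tcrossprod(z1 / psi)
      }
    }
    step <- solve(hess, grad)
    beta_new <- beta + step
    if (max(abs(step)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(coef = beta, loglik = loglik(beta))
}

# Brute-force Harrell concordance: all pairs, comparable when the earlier
# time is an event and times differ; tied predictions count 1/2.
oracle_cindex <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      den <- den + 1
      if (score[early] > score[late]) num <- num + 1
      else if (score[early] == score[late]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Exhaustive threshold search over all midpoints between consecutive sorted
# unique scores, maximizing the binary-indicator concordance; smallest
# maximizer returned.
oracle_best_threshold <- function(score, time, event) {
  us <- sort(unique(score))
  cand <- (us[-length(us)] + us[-1]) / 2
  cvals <- vapply(cand, function(tau) {
    oracle_cindex(time, event, as.numeric(score > tau))
  }, numeric(1))
  cand[which.max(cvals)]
}

# Definitional Benjamini-Hochberg step-up: q_(i) = min_{j >= i} n p_(j) / j,
# capped at 1, in the original order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, n * p[o] / seq_len(n))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Hand product-limit estimator: survival at each distinct event time.
oracle_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Small survival datasets with continuous (tie-free) times.
make_toy_surv <- function(n, seed = 1, p_event = 0.7) {
  set.seed(seed)
  list(time = round(rexp(n, 0.1) + runif(n), 6),
       event = rbinom(n, 1, p_event))
}

# A hand-specified single-protein fixture: one reference peptide with heavy
# standard, one 3-glycan occupancy site, plus QC pool rows; intensities are
# chosen so every derived value is computable by hand.
make_mini_fixture <- function() {
  manifest <- data.frame(
    analyte_id = c("P1|REFPEPK", "P1|REFPEPK*", "P1|GLYPEPK@N5|5401",
                   "P1|GLYPEPK@N5|5402", "P1|GLYPEPK@N5|5510"),
    protein = "P1",
    peptide = c("REFPEPK", "REFPEPK", "GLYPEPK", "GLYPEPK", "GLYPEPK"),
    site = c(NA, NA, 5L, 5L, 5L),
    glycan = c(NA, NA, "5401", "5402", "5510"),
    linkage = c("none", "none", "N", "N", "N"),
    kind = c("peptide", "heavy_standard", rep("glycopeptide", 3)),
    reference_peptide_id = "P1|REFPEPK",
    heavy_standard_id = c("P1|REFPEPK*", NA, NA, NA, NA),
    spike_concentration = c(10, 10, NA, NA, NA),
    site_normalization = c(NA, NA, rep("site_occupancy", 3)),
    site_key = c("P1|REFPEPK", "P1|REFPEPK", rep("P1|GLYPEPK|5", 3)),
    stringsAsFactors = FALSE
  )
  # constant QC intensities (flat drift); two test samples
  vals <- rbind(
    QC001 = c(100, 50, 10, 20, 30),
    S1    = c(200, 50, 20, 30, 50),
    S2    = c(100, 25, 40, 40, 20),
    QC002 = c(100, 50, 10, 20, 30)
  )
  colnames(vals) <- manifest$analyte_id
  raw <- glycosurv:::new_glyco_raw(
    vals, data.frame(sample_id = rownames(vals),
                     injection_order = 1:4,
                     is_qc_pool = c(TRUE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE))
  list(manifest = manifest, raw = raw)
}

# Minimal clinical table builder for unit tests.
make_clinical <- function(time, event, seed = 1, pfs_frac = 0.5) {
  set.seed(seed)
  n <- length(time)
  data.frame(patient_id = sprintf("PT%03d", seq_len(n)),
             age = round(runif(n, 40, 80)),
             sex = rep_len(c("male", "female"), n),
             regimen = rep_len(c("anti-PD-1", "anti-PD-1 + anti-CTLA-4"), n),
             subtype = rep_len(c("cutaneous", "mucosal"), n),
             ldh_category = rep_len(c("<ULN", "1-2xULN"), n),
             ecog = rep_len(c("0", "1"), n),
             braf = rep_len(c("mutant", "wild-type"), n),
             m_stage = rep_len(c("M0", "M1c"), n),
             line_of_therapy = rep_len(c("first", "later"), n),
             os_time = time, os_event = as.logical(event),
             pfs_time = time * pfs_frac, pfs_event = as.logical(event),
             stringsAsFactors = FALSE)
}
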