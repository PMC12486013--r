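# Independent oracles, deliberately written from the definitions with
# different code paths than the implementation they check.

# Brute-force AUC: exhaustive case/control pair enumeration.
oracle_auc <- function(scores, outcome) {
  cases <- scores[outcome == 1]
  controls <- scores[outcome == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Fixed-effects inverse-variance meta from the closed form, one variant.
oracle_meta <- function(betas, ses) {
  w <- 1 / ses^2
  b <- sum(w * betas) / sum(w)
  s <- sqrt(1 / sum(w))
  c(beta = b, se = s)
}

# Greedy clumping re-derived from the definition: full r2 matrix upfront,
# explicit set bookkeeping.
oracle_clump <- function(ss, dosages, r2_threshold, window_kb) {
  r2 <- suppressWarnings(cor(dosages))^2
  r2[!is.finite(r2)] <- 0
  remaining <- seq_len(nrow(ss))
  kept <- integer(0)
  while (length(remaining) > 0) {
    o <- remaining[order(ss$p[remaining], ss$chrom[remaining],
                         ss$pos[remaining])]
    idx <- o[1]
    kept <- c(kept, idx)
    near <- remaining[ss$chrom[remaining] == ss$chrom[idx] &
                        abs(ss$pos[remaining] - ss$pos[idx]) <=
                          window_kb * 1000 &
                        remaining != idx]
    kill <- near[r2[idx, near] >= r2_threshold]
    remaining <- setdiff(remaining, c(idx, kill))
  }
  sort(kept)
}

# Nested-loop PRS scoring.
oracle_score <- function(D, weights) {
  out <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    s <- 0
    for (j in seq_len(ncol(D))) s <- s + D[i, j] * weights[j]
    out[i] <- s
  }
  out
}

# Independence + maximality checker for unrelated-set selection.
oracle_check_unrelated <- function(retained, all_samples, kin, threshold) {
  rel <- kin[kin$kinship >= threshold, , drop = FALSE]
  for (r in seq_len(nrow(rel))) {
    if (rel$id1[r] %in% retained && rel$id2[r] %in% retained)
      return("related pair retained")
  }
  for (d in setdiff(all_samples, retained)) {
    partners <- c(rel$id2[rel$id1 == d], rel$id1[rel$id2 == d])
    if (!any(partners %in% retained)) return(paste("not maximal:", d))
  }
  "ok"
}

# Logistic log-likelihood for the optim cross-check.
logistic_negll <- function(par, X, y) {
  eta <- X %*% par
  -sum(y * eta - log1p(exp(eta)))
}
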