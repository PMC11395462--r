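# Univariate partial least squares (PLS1, NIPALS) used as the binary
# classifier of the integration step.  Kept minimal and allocation-light:
# the recursive feature elimination loop refits it thousands of times on
# small matrices.  Validated against an independent PLS implementation in
# the test suite.

pls1_fit <- function(x, y, ncomp) {
  xm <- colMeans(x)
  ym <- mean(y)
  e <- sweep(x, 2, xm, "-")
  f <- y - ym
  k <- ncol(x)
  ncomp <- min(ncomp, k, nrow(x) - 1L)
  w_mat <- matrix(0, k, ncomp)
  p_mat <- matrix(0, k, ncomp)
  q_vec <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- e %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p <- crossprod(e, t_sc) / tt
    q <- sum(f * t_sc) / tt
    e <- e - tcrossprod(t_sc, p)
    f <- f - q * t_sc
    w_mat[, a] <- w
    p_mat[, a] <- p
    q_vec[a] <- q
    a_used <- a
  }
  if (a_used == 0L) {
    coef <- numeric(k)
  } else {
    w_mat <- w_mat[, seq_len(a_used), drop = FALSE]
    p_mat <- p_mat[, seq_len(a_used), drop = FALSE]
    coef <- as.numeric(w_mat %*% solve(crossprod(p_mat, w_mat),
                                       q_vec[seq_len(a_used)]))
  }
  list(coef = coef, intercept = ym - sum(xm * coef), ncomp = a_used,
       features = colnames(x))
}

pls1_predict <- function(fit, x) {
  as.numeric(x %*% fit$coef) + fit$intercept
}

# rank-based (tie-corrected) AUC of continuous scores against binary labels;
# equals the Wilcoxon rank-sum statistic
auc_rank <- function(scores, labels) {
  pos <- labels > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
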