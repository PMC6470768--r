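# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# SVD-based PLS: per component, the X-weight is the first left singular
# vector of the cross-covariance X'Y; X is deflated on the score.
svd_pls_oracle <- function(X, Y, n_components) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  E <- X
  W <- matrix(0, ncol(X), n_components)
  Tm <- matrix(0, nrow(X), n_components)
  for (a in seq_len(n_components)) {
    sv <- svd(crossprod(E, Y))
    w <- sv$u[, 1]
    tt <- E %*% w
    p <- crossprod(E, tt) / sum(tt^2)
    E <- E - tt %*% t(p)
    W[, a] <- w
    Tm[, a] <- tt
  }
  list(W = W, T = Tm)
}

# VIP by literal formula evaluation from a model's raw pieces.
vip_bruteforce <- function(W, ssy) {
  p <- nrow(W)
  num <- rep(0, p)
  for (a in seq_len(ncol(W))) {
    wa <- W[, a]
    num <- num + ssy[a] * (wa / sqrt(sum(wa^2)))^2
  }
  sqrt(p * num / sum(ssy))
}

# Benjamini-Hochberg by the min-over-tail definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(ord == i)  # rank of p[i]
    tail_idx <- ord[j:m]
    q[i] <- min(1, min(m * p[tail_idx] / seq(j, m)))
  }
  q
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all rank
# assignments (no ties assumed).
mw_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx)
    sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  # two-sided: assignments at least as extreme (distance from the mean)
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}

# OLS by the normal equations.
ols_normal_equations <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  xtx <- solve(crossprod(Xd))
  beta <- xtx %*% crossprod(Xd, y)
  resid <- y - Xd %*% beta
  s2 <- sum(resid^2) / (nrow(Xd) - ncol(Xd))
  se <- sqrt(diag(xtx) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = nrow(Xd) - ncol(Xd))
  list(beta = drop(beta), se = drop(se), p = drop(p))
}

# Empirical standardized group difference (pooled-SD Cohen's d).
cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}

# Small random fixture: two-class data with an optional planted shift.
make_two_class <- function(n_per_class, p, shift = 0, n_shifted = p,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  g <- rep(c("a", "b"), each = n_per_class)
  X[g == "a", seq_len(n_shifted)] <- X[g == "a", seq_len(n_shifted)] + shift
  colnames(X) <- sprintf("f%02d", seq_len(p))
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  list(X = X, g = g)
}

# default-sized synthetic study, shared by several tests
make_default_study <- function(seed = 1, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  meta <- generate_cohort(cfg)
  gen <- generate_blocks(meta, cfg)
  list(cfg = cfg, meta = meta, tables = gen$tables, truth = gen$truth,
       bio = meta[!meta$is_qc, ])
}
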