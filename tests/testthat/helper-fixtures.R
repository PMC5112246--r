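# Small in-code fixtures shared across test files.

# Minimal valid design sheet with explicit covariate values.
tiny_design <- function(n = 4, smoking = rep(0, n), accp = rep(0, n),
                        dmard = rep(0, n), age = rep(50, n),
                        sex = rep(1, n)) {
  pair_design(data.frame(
    pair_id = sprintf("p%02d", seq_len(n)),
    case_sample = sprintf("p%02d_case", seq_len(n)),
    control_sample = sprintf("p%02d_ctrl", seq_len(n)),
    smoking = smoking, accp = accp, dmard = dmard, age = age, sex = sex,
    stringsAsFactors = FALSE))
}

# Beta matrix whose case/control columns realise the given delta matrix
# around a 0.5 baseline (delta must stay within +/- 1).
betas_from_delta <- function(delta, design) {
  case <- 0.5 + delta / 2
  control <- 0.5 - delta / 2
  b <- cbind(case, control)
  colnames(b) <- c(design$case_sample, design$control_sample)
  rownames(b) <- rownames(delta)
  b
}

# Evenly spaced single-cluster manifest.
flat_manifest <- function(n, gap = 100, chrom = "chr1", start = 1000) {
  manifest(data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
                      chrom = chrom,
                      pos = start + gap * (seq_len(n) - 1L),
                      stringsAsFactors = FALSE))
}

# Naive reference implementations, written independently of the package's
# vectorised engine: straightforward loops for the tricube local-linear
# smoother and threshold run detection.
naive_smooth <- function(pos, y, h = 1000, min_ll = 7) {
  m <- length(pos)
  if (m <= 2) return(y)
  if (m < min_ll) {
    out <- numeric(m)
    for (k in seq_len(m)) {
      nb <- max(1, k - 1):min(m, k + 1)
      out[k] <- mean(y[nb])
    }
    return(out)
  }
  out <- numeric(m)
  for (k in seq_len(m)) {
    d <- abs(pos - pos[k])
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    fit <- lm(y ~ I(pos - pos[k]), weights = w)
    out[k] <- coef(fit)[1]
  }
  out
}

naive_bump_areas <- function(sm, upper, lower) {
  areas <- c(); cur <- 0; state <- 0
  for (v in c(sm, 0)) {
    s <- if (v > upper) 1 else if (v < lower) -1 else 0
    if (s != state && cur > 0) { areas <- c(areas, cur); cur <- 0 }
    if (s != 0) cur <- cur + abs(v)
    state <- s
  }
  areas
}

# Closed-form OLS + t oracle, written independently of the package's
# fitting code: normal equations, residual variance, two-sided t.
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tval <- as.numeric(b) / se
  list(coef = as.numeric(b), se = se,
       p = 2 * pt(-abs(tval), df), df = df)
}
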