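# Independent oracles, coded separately from the implementation paths they
# check: sums-of-squares ICC, brute-force signed-rank enumeration, and a
# table-interpolation inverse of the ECA length-at-angle map.

# ICC(2,1)/(2,k) from raw sums of squares (no aov)
icc_oracle <- function(mat, form = c("single", "average")) {
  form <- match.arg(form)
  n <- nrow(mat)
  k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((mat - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# two-sided paired signed-rank p by enumerating all 2^n sign patterns
wilcox_exact_enum <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# dense-lookup inverse of the ECA: linear interpolation of the tabulated
# percentage grid (1-degree steps plus the 0-degree intercept)
invert_eca_table_oracle <- function(A, B, L, params = cochlear_params()) {
  tab <- pbtl_table(params)
  theta <- c(0, tab$theta_deg)
  pct <- c(pbtl(0, params), tab$pbtl_percent)
  btl <- btl_eca(A, B, params = params)
  stats::approx(pct, theta, xout = 100 * L / btl)$y
}
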