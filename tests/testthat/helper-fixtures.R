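# shared fixtures built in code

toy_expr <- function() {
  structure(
    data.frame(
      sample_id = c("c1", "c2", "p1"),
      class_label = c("CTR", "CTR", "DMD"),
      m1 = c(2, 4, 6),
      m2 = c(1, 1, 2),
      stringsAsFactors = FALSE
    ),
    units = "calibrated"
  )
}

# the worked 3-item linkage example: d(A,B)=2, d(A,C)=4, d(B,C)=6
abc_dist <- function() {
  m <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  stats::as.dist(m)
}

random_dist <- function(n) {
  pts <- matrix(stats::rnorm(n * 3), n)
  rownames(pts) <- paste0("s", seq_len(n))
  stats::dist(pts)
}

# closed-form OLS via the normal equations, independent of lm()
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# mean of a normal censored below at 0
censored_mean <- function(mu, sd) {
  if (sd == 0) return(max(mu, 0))
  mu * stats::pnorm(mu / sd) + sd * stats::dnorm(mu / sd)
}
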