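# Explicit sum-of-squares ANOVA oracle, independent of the package's
# implementation: every quantity from raw sums.
oracle_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssb <- 0; ssw <- 0; ssc <- 0; sse <- 0
  rmeans <- apply(x, 1, function(r) sum(r) / k)
  cmeans <- apply(x, 2, function(c) sum(c) / n)
  for (i in 1:n) {
    ssb <- ssb + k * (rmeans[i] - gm)^2
    for (j in 1:k) {
      ssw <- ssw + (x[i, j] - rmeans[i])^2
      sse <- sse + (x[i, j] - rmeans[i] - cmeans[j] + gm)^2
    }
  }
  for (j in 1:k) ssc <- ssc + n * (cmeans[j] - gm)^2
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  msr <- msb; msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  list(icc1 = (msb - msw) / (msb + (k - 1) * msw),
       icc_a1 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

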