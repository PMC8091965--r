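# brute-force within-subjects sum-of-squares oracle for the
# repeated-measures ANOVA (explicit loops, no matrix shortcuts)
rm_anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_cond <- 0; ss_subj <- 0; ss_tot <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(m[, j]) - g)^2
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(m[i, ]) - g)^2
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (m[i, j] - g)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(f = f, p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}
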