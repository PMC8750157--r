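# Shared fixtures: the study's acquisition constants and small forward-model
# generators used across tests.

b_ladder <- c(0, 10, 25, 50, 75, 150, 300, 500, 750, 1000)
vfa_angles <- c(2, 5, 10, 15, 20)
dce_tr <- 4.8
dce_alpha <- 12

# Brute-force SUVpeak: exhaustive triple loop over all centers, independent
# of the package's offset-table implementation.
brute_suv_peak <- function(vox, spacing) {
  dims <- dim(vox)
  r2 <- (3 * 1000 / (4 * pi))^(2 / 3)
  reach <- ceiling(sqrt(r2) / spacing)
  best <- -Inf
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      vals <- numeric(0)
      for (di in -reach[1]:reach[1]) for (dj in -reach[2]:reach[2])
        for (dk in -reach[3]:reach[3]) {
          x <- i + di; y <- j + dj; z <- k + dk
          if (x < 1 || x > dims[1] || y < 1 || y > dims[2] ||
              z < 1 || z > dims[3]) next
          if ((di * spacing[1])^2 + (dj * spacing[2])^2 +
              (dk * spacing[3])^2 <= r2)
            vals <- c(vals, vox[x, y, z])
        }
      m <- mean(vals)
      if (m > best) best <- m
    }
  best
}

# O(n^2) pairwise AUC oracle (ties one half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# O(n^2) Harrell's C oracle.
brute_harrell_c <- function(lp, time, event) {
  conc <- 0; ties <- 0; usable <- 0
  n <- length(lp)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] == 1 && event[j] == 1) { usable <- usable + 1; ties <- ties + 1 }
      next
    }
    s <- if (time[i] < time[j]) i else j
    l <- if (time[i] < time[j]) j else i
    if (event[s] != 1) next
    usable <- usable + 1
    if (lp[s] > lp[l]) conc <- conc + 1
    else if (lp[s] == lp[l]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / usable
}
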