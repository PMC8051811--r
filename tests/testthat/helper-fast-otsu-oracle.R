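# Vectorized exhaustive Otsu oracle for 8-bit integer images: scans every
# split "<= v vs > v" over the gray levels 0..254 using exact value-level
# cumulative moments (no histogram binning involved).
oracle_otsu_split_fast <- function(x) {
  x <- as.integer(x)
  cnt <- tabulate(x + 1L, nbins = 256L)
  vals <- 0:255
  n <- length(x)
  cs <- cumsum(cnt * vals)
  cs2 <- cumsum(cnt * vals^2)
  cn <- cumsum(cnt)
  v <- 0:254
  n0 <- cn[v + 1L]; n1 <- n - n0
  ok <- n0 > 0L & n1 > 0L
  m0 <- cs[v + 1L] / n0; m1 <- (cs[256] - cs[v + 1L]) / n1
  v0 <- cs2[v + 1L] / n0 - m0^2
  v1 <- (cs2[256] - cs2[v + 1L]) / n1 - m1^2
  s <- (n0 / n) * v0 + (n1 / n) * v1
  s[!ok] <- Inf
  best <- which.min(s)
  list(split = v[best], sigma_w2 = s[best])
}
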