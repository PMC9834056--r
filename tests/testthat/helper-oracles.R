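# Brute-force oracles, independent of the implementation paths they check.

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracleMatchGrid <- function(left, right) {
  l <- strsplit(left, "")[[1]]
  r <- strsplit(right, "")[[1]]
  m <- matrix(0, length(l), length(r))
  for (i in seq_along(l)) for (j in seq_along(r))
    if (l[i] == r[j] && l[i] != "N") m[i, j] <- 1
  m
}

# max junction-spanning match run, scanning both directions base by base
oracleMhLength <- function(left, right) {
  l <- strsplit(left, "")[[1]]
  r <- strsplit(right, "")[[1]]
  w <- length(l) / 2
  runFrom <- function(inc, exc) {
    k <- 0
    for (j in 0:(w - 1)) {
      a <- inc[w + 1 + j]     # label +j
      b <- exc[w - j]         # label -(j+1)
      if (a == b && a != "N") k <- k + 1 else break
    }
    k
  }
  max(runFrom(l, r), runFrom(r, l))
}

# exhaustive templated-insert search over every start offset x 4 orientations
# x 2 windows
oracleTemplated <- function(insert, windowA, windowB, minlen = 3) {
  if (nchar(insert) == 0) return("no_insertion")
  if (nchar(insert) < minlen) return("miscellaneous")
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  comp1 <- function(s) chartr("ACGTN", "TGCAN", s)
  forms <- unique(c(insert, rev1(insert), comp1(insert), rev1(comp1(insert))))
  found <- FALSE
  for (wd in c(windowA, windowB)) {
    for (f in forms) {
      L <- nchar(f)
      if (L > nchar(wd)) next
      for (i in 1:(nchar(wd) - L + 1))
        if (substr(wd, i, i + L - 1) == f) { found <- TRUE; break }
      if (found) break
    }
    if (found) break
  }
  if (found) "templated" else "miscellaneous"
}

# Benjamini-Hochberg step-up, spelled out
oracleBH <- function(p, m = length(p)) {
  ord <- order(p)
  q <- numeric(length(p))
  sorted <- p[ord] * m / seq_along(p)
  # step-up: running minimum from the largest rank down
  for (i in seq_along(sorted)) sorted[i] <- min(sorted[i:length(sorted)])
  q[ord] <- pmin(sorted, 1)
  q
}

# exact upper-tail binomial sum
oracleBinomTail <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

oracleLcp <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  k <- 0
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] == b[i] && a[i] != "N") k <- k + 1 else break
  }
  k
}
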