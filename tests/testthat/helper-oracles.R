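# Independent brute-force oracles used to check the package's dynamic
# programming, exact-test and classification code paths.

# 4x4 pair-weight matrix over A,C,G,U for the enumeration oracle
oracle_weight_matrix <- function(pw) {
  w <- matrix(0, 4, 4)
  w[1, 4] <- w[4, 1] <- pw[["AU"]]
  w[2, 3] <- w[3, 2] <- pw[["GC"]]
  w[3, 4] <- w[4, 3] <- pw[["GU"]]
  w
}

# exhaustive enumeration of all nested structures, Boltzmann-weighted;
# returns the pair-probability matrix (independent of the DP code)
oracle_enum_bpp <- function(sequence, pw, min_loop = 3) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  code <- c(A = 1, C = 2, G = 3, U = 4, T = 4)[chars]
  wmat <- oracle_weight_matrix(pw)
  n <- length(code)
  rec <- function(i, j) {
    if (i > j) return(list(list(pairs = matrix(0L, 0, 2), w = 1)))
    out <- rec(i + 1, j)
    if (i + min_loop + 1 <= j) for (k in (i + min_loop + 1):j) {
      w <- wmat[code[i], code[k]]
      if (w <= 0) next
      for (s1 in rec(i + 1, k - 1)) for (s2 in rec(k + 1, j)) {
        out[[length(out) + 1L]] <- list(pairs = rbind(s1$pairs, s2$pairs, c(i, k)),
                                        w = s1$w * s2$w * w)
      }
    }
    out
  }
  p <- matrix(0, n, n)
  if (n < min_loop + 2) return(p)
  ss <- rec(1, n)
  Z <- sum(vapply(ss, `[[`, 1, "w"))
  for (s in ss) if (nrow(s$pairs) > 0) for (r in seq_len(nrow(s$pairs))) {
    p[s$pairs[r, 1], s$pairs[r, 2]] <- p[s$pairs[r, 1], s$pairs[r, 2]] + s$w
  }
  (p + t(p)) / Z
}

# direct hypergeometric summation from binomial coefficients (no dhyper),
# same tie convention as the implementation (relative tolerance 1 + 1e-7)
oracle_fisher_p <- function(x, m, n, k) {
  sup <- max(0, k - n):min(k, m)
  d <- exp(lchoose(m, sup) + lchoose(n, k - sup) - lchoose(m + n, k))
  min(1, sum(d[d <= d[match(x, sup)] * (1 + 1e-7)]))
}

# straight-line transcription of the class rules with I > R > S precedence
oracle_classify <- function(tc, ts, s_delta = -0.8, r_level = 0.8,
                            i_control_max = 0, i_delta = 1) {
  vapply(seq_along(tc), function(g) {
    d <- ts[g] - tc[g]
    if (tc[g] <= i_control_max && d >= i_delta) return("I")
    if (tc[g] >= r_level && ts[g] >= r_level) return("R")
    if (d <= s_delta) return("S")
    "U"
  }, "")
}

# regex-free position scan for upstream AUGs
oracle_count_uaug <- function(utr5) {
  n <- nchar(utr5)
  if (n < 3) return(0L)
  hits <- 0L
  for (i in 1:(n - 2)) if (substr(utr5, i, i + 2) == "ATG") hits <- hits + 1L
  hits
}

# random transcript sequence for feature-extraction checks
random_transcript <- function(utr5_len, n_codons, utr3_len) {
  paste(sample(c("A", "C", "G", "T"), utr5_len + 3 * n_codons + utr3_len,
               replace = TRUE), collapse = "")
}
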