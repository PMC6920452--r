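# small builders shared across test files

# random non-degenerate count matrix with positive margins
random_count_matrix <- function(nr = 4, nc = 3, N = 60) {
  repeat {
    m <- matrix(stats::rmultinom(1, N, rep(1 / (nr * nc), nr * nc)), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# tiny set of equal-length sequences built from a base sequence plus
# substitutions at given positions
make_seqs <- function(base, subs = list()) {
  out <- c(ref = base)
  for (nm in names(subs)) {
    s <- base
    for (k in seq_len(nrow(subs[[nm]]))) {
      pos <- subs[[nm]][k, 1]
      substr(s, pos, pos) <- rownames(subs[[nm]])[k]
    }
    out[nm] <- s
  }
  out
}

# brute-force nucleotide diversity: loop over all pairs of sequences
brute_pi <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[[i]], "")[[1]]
    b <- strsplit(seqs[[j]], "")[[1]]
    ok <- a != "N" & b != "N"
    tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
  }
  tot / choose(n, 2)
}

# brute-force haplotype diversity from counts
brute_h <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# brute-force BH step-up: find largest k with p_(k) <= k q / m
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(k)) flags[ord[seq_len(max(k))]] <- TRUE
  flags
}

# a writable temp dir per test
local_dir <- function(env = parent.frame()) {
  d <- tempfile("haplospat_test_")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
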