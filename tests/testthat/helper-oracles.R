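# Independent oracles used across tests; none of these call the package's
# implementation of the quantity they check.

# naive IUPAC-aware primer scan: checks every offset on both strands
iupac_expand <- c(
  A = "A", C = "C", G = "G", T = "T",
  M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
  V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT"
)

iupac_char_match <- function(p, s) {
  # pattern char p (ambiguity honoured) against literal subject char s
  grepl(s, iupac_expand[[p]], fixed = TRUE)
}

naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

naive_scan <- function(template, primer, max_mismatches = 0) {
  scan_one <- function(pat, strand) {
    pc <- strsplit(pat, "")[[1]]
    tc <- strsplit(template, "")[[1]]
    np <- length(pc); nt <- length(tc)
    hits <- list()
    if (np > nt) return(hits)
    for (i in seq_len(nt - np + 1)) {
      mm <- sum(!mapply(iupac_char_match, pc, tc[i:(i + np - 1)]))
      if (mm <= max_mismatches) {
        hits[[length(hits) + 1]] <- data.frame(start = i, end = i + np - 1,
                                               strand = strand)
      }
    }
    hits
  }
  rows <- c(scan_one(primer, "+"), scan_one(naive_revcomp(primer), "-"))
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# numeric time integral of an exponential trajectory x0 * exp(r t) over [0, T]
numeric_time_integral <- function(x0, r, T, n = 20001) {
  t <- seq(0, T, length.out = n)
  x <- x0 * exp(r * t)
  sum((x[-1] + x[-n]) / 2) * (T / (n - 1)) # trapezoid, equal spacing
}

# bisection inverse of f -> bacterial production, independent of the closed form
bisect_critical_f <- function(target, npp, D, eb, ec, lo = 0, hi = 1 - 1e-12,
                              tol = 1e-13) {
  pb_of_f <- function(f) {
    ea <- f / (1 - f) * npp
    eb * (ea - D) / (1 - eb * (1 - ec))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pb_of_f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# small default-like simulation shared by a few tests (cheap: coarse step is
# NOT used -- the fixed 0.01 d step is part of the contract)
cached_default_sim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulate_chemostat(sim_config(seed = 11))
    sim
  }
})
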