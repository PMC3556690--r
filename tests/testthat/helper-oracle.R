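# Brute-force digestion oracle: enumerate every substring of the protein and
# keep those whose two boundaries are valid tryptic cut points (or termini)
# and that span at most `mc` internal cut points. Independent of
# digest_protein(), which builds peptides from consecutive fragments instead.
oracle_digest <- function(sequence, mc) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  iscut <- logical(n)
  if (n >= 2L) {
    i <- seq_len(n - 1L)
    iscut[i] <- (chars[i] == "K" | chars[i] == "R") & chars[i + 1L] != "P"
  }
  cum <- cumsum(iscut)                       # cuts at positions 1..i
  boundary_ok <- function(i) i == 0L | i == n | iscut[pmax(i, 1L)]

  ab <- expand.grid(a = seq_len(n), b = seq_len(n))
  ab <- ab[ab$a <= ab$b, ]
  left_ok <- boundary_ok(ab$a - 1L)
  right_ok <- boundary_ok(ab$b)
  cum0 <- c(0L, cum)                         # cum0[i + 1] = cuts at <= i
  internal <- cum0[ab$b] - cum0[ab$a]        # cuts at positions a..b-1
  keep <- left_ok & right_ok & internal <= mc
  out <- data.frame(start = ab$a[keep], end = ab$b[keep])
  out <- out[order(out$start, out$end), ]
  out$peptide <- substring(sequence, out$start, out$end)
  rownames(out) <- NULL
  out
}

random_sequence <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
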