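# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths (regex scanning, cumulative-sum series) so a
# bug cannot cancel out of both sides of an assertion.

# brute-force motif scan: slide a window, check residue membership per position
oracle_scan <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  sets <- lapply(parts, function(p) {
    if (p == "X") NULL else strsplit(gsub("\\[|\\]", "", p), "")[[1]]
  })
  w <- length(sets)
  hits <- integer()
  for (start in seq_len(max(length(chars) - w + 1L, 0L))) {
    ok <- TRUE
    for (j in seq_len(w)) {
      r <- chars[start + j - 1L]
      if (is.null(sets[[j]])) next            # wildcard: anything, incl. X
      if (!(r %in% sets[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# enumerate every omega-nameable structure for a chain length: all
# methylene-interrupted (spacing exactly 3) position sets, keyed by the
# terminal position; independent of the package's expansion rule
oracle_omega_structures <- function(chain, max_d = 6L) {
  out <- list()
  for (d in 1:max_d) {
    for (p_max in seq(2L, chain - 1L)) {
      pos <- p_max - 3L * (seq_len(d) - 1L)
      if (min(pos) < 2L) next
      out[[length(out) + 1L]] <- list(
        shorthand = sprintf("%d:%dn-%d", chain, d, chain - p_max),
        positions = sort(pos))
    }
  }
  out
}

# sample() treats a length-1 numeric as 1:n; this always picks an element
pick1 <- function(x) x[sample.int(length(x), 1L)]

# a random valid fatty acid; positions restricted to the DMOX-detectable
# window when detectable = TRUE
rand_fa <- function(chain = NULL, max_bonds = 4L, detectable = TRUE) {
  chain <- chain %||% pick1(8:22)
  lo <- if (detectable) 4L else 2L
  hi <- if (detectable) chain - 2L else chain - 1L
  pos <- integer()
  n_target <- pick1(0:max_bonds)
  avail <- seq(lo, hi)
  while (length(pos) < n_target && length(avail)) {
    p <- pick1(avail)
    pos <- sort(c(pos, p))
    avail <- setdiff(avail, (p - 1L):(p + 1L))
  }
  fatty_acid(chain, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
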