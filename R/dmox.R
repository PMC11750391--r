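#' DMOX fragment-series prediction
#'
#' Electron-ionization spectra of 4,4-dimethyloxazoline (DMOX) fatty-acid
#' derivatives show a homologous fragment series in which each successive
#' fragment retains one more acyl carbon. At unit-mass resolution the series
#' is anchored at m/z 113 (2 acyl carbons) and 126 (3 carbons) and then grows
#' by +14 per CH2 — except across a carbon that starts a double bond, where
#' the increment is +12. A gap of 12 a.m.u. between the fragments with n-1
#' and n carbons therefore localises a double bond at delta position n. The
#' molecular ion is the last series member plus 15 (the terminal methyl).
#'
#' @param x a `fatty_acid` or shorthand string with chain length >= 4.
#' @return an object of class `"dmox_series"`: a tibble with columns
#'   `n_carbons` (2 to chain length - 1) and `mz`, with attributes
#'   `molecular_ion` and `fa` (canonical delta name).
#' @examples
#' s <- predict_dmox("20:2^Δ5,11^")
#' s[s$n_carbons %in% c(10, 11), ]  # the 222/234 gap of 12
#' @export
predict_dmox <- function(x) {
  fa <- as_fatty_acid(x)
  if (fa$chain < 4L) abort_input("DMOX series requires a chain of >= 4 carbons.")
  n <- 2:(fa$chain - 1L)
  out <- tibble(n_carbons = n, mz = dmox_series_mz(fa$chain, fa$db))
  attr(out, "molecular_ion") <- out$mz[nrow(out)] + 15L
  attr(out, "fa") <- fa_to_delta(fa)
  class(out) <- c("dmox_series", class(out))
  out
}

# m/z of the n-carbon fragments (n = 2..chain-1) for double bonds `db`:
# saturated baseline 126 + 14*(n-3), minus 2 per double bond at position <= n
dmox_series_mz <- function(chain, db) {
  n <- 2:(chain - 1L)
  base <- ifelse(n == 2L, 113L, 126L + 14L * (n - 3L))
  shift <- vapply(n, function(k) 2L * sum(db >= 4L & db <= k), 0L)
  as.integer(base - shift)
}

#' @export
print.dmox_series <- function(x, ...) {
  cat(sprintf("<dmox_series> %s  molecular ion m/z %d\n",
              attr(x, "fa"), molecular_ion(x)))
  print(as_tibble(x), n = nrow(x))
  invisible(x)
}

#' @rdname predict_dmox
#' @param s a `dmox_series`.
#' @export
molecular_ion <- function(s) {
  if (inherits(s, "dmox_series")) return(attr(s, "molecular_ion"))
  fa <- as_fatty_acid(s)
  mz <- dmox_series_mz(fa$chain, fa$db)
  as.integer(mz[length(mz)] + 15L)
}

#' DMOX diagnostic-ion rule table
#'
#' Some double-bond positions are read from a characteristic low-mass ion
#' rather than a series gap: delta-5 desaturation gives a diagnostic ion at
#' m/z 153. `dmox_diagnostic_rules()` returns the rule table (extensible by
#' binding extra rows); `diagnostic_ions()` applies it to a structure.
#'
#' @return `dmox_diagnostic_rules()`: a tibble with columns `position`, `mz`.
#' @export
dmox_diagnostic_rules <- function() {
  tibble(position = 5L, mz = 153L)
}

#' @rdname dmox_diagnostic_rules
#' @param x a `fatty_acid` or shorthand string.
#' @param rules a rule table as from `dmox_diagnostic_rules()`.
#' @return `diagnostic_ions()`: the subset of `rules` whose positions occur
#'   in `x` (zero rows when none apply).
#' @examples
#' diagnostic_ions("20:4^Δ5,11,14,17^")  # position 5 -> m/z 153
#' @export
diagnostic_ions <- function(x, rules = dmox_diagnostic_rules()) {
  fa <- as_fatty_acid(x)
  rules[rules$position %in% fa$db, , drop = FALSE]
}

# all double-bond position sets within [4, chain-2], up to `max_bonds` bonds,
# pairwise spacing >= 2; memoised per (chain, max_bonds)
candidate_bond_sets <- function(chain, max_bonds = 6L) {
  key <- sprintf("cand_%d_%d", chain, max_bonds)
  if (!is.null(the[[key]])) return(the[[key]])
  pos <- seq(4L, chain - 2L)
  sets <- list(integer())
  for (k in seq_len(min(max_bonds, length(pos)))) {
    cmb <- combn(pos, k)
    ok <- apply(cmb, 2L, function(s) all(diff(s) >= 2L))
    sets <- c(sets, lapply(which(ok), function(j) cmb[, j]))
  }
  the[[key]] <- sets
  sets
}

#' Infer double-bond positions from a DMOX spectrum
#'
#' Enumerates every candidate double-bond set with positions in the
#' detectable range `[4, chain_length - 2]` (up to `max_bonds` bonds, spacing
#' >= 2), predicts the full peak set for each (fragment series, diagnostic
#' ions and molecular ion) and scores it by the fraction of predicted peaks
#' present in the observed spectrum at exact unit mass. Intensities are
#' ignored beyond peak presence. The best-scoring candidate wins; ties are
#' broken in favour of fewer double bonds, then the lexicographically
#' smallest position set. Structures with double bonds outside the
#' detectable range are out of model and will not be proposed.
#'
#' @param spectrum a tibble with columns `mz` (and optionally `intensity`),
#'   or an integer vector of observed m/z values.
#' @param chain_length acyl chain length (from the molecular ion or prior
#'   knowledge).
#' @param floor minimum acceptable score; below it the spectrum is declared
#'   uninterpretable (error of class `"pufapath_spectrum_error"`).
#' @param max_bonds largest candidate double-bond count.
#' @return an object of class `"dmox_inference"`: a list with the inferred
#'   `fa` ([fatty_acid()]), its `score`, the `chain_length`, and a
#'   `candidates` tibble (`positions` label, `n_bonds`, `score`) sorted by
#'   rank.
#' @examples
#' s <- predict_dmox("20:2^Δ5,11^")
#' obs <- c(s$mz, molecular_ion(s), 153)
#' infer_double_bonds(obs, 20)
#' @export
infer_double_bonds <- function(spectrum, chain_length, floor = 0.5,
                               max_bonds = 6L) {
  chain_length <- as.integer(chain_length)
  if (chain_length < 6L) abort_input("`chain_length` must be >= 6.")
  mz_obs <- if (is.data.frame(spectrum)) spectrum$mz else spectrum
  mz_obs <- unique(as.integer(round(mz_obs)))
  if (!length(mz_obs) || any(mz_obs <= 0L)) {
    abort_input("spectrum must contain positive m/z values.")
  }
  rules <- dmox_diagnostic_rules()
  max_mz <- 126L + 14L * (chain_length - 3L) + 15L
  present <- logical(max_mz + 1L)
  present[mz_obs[mz_obs <= max_mz] + 1L] <- TRUE
  sets <- candidate_bond_sets(chain_length, max_bonds)
  scores <- vapply(sets, function(db) {
    mz <- dmox_series_mz(chain_length, db)
    pred <- c(mz, mz[length(mz)] + 15L, rules$mz[rules$position %in% db])
    pred <- unique(pred)
    mean(present[pred + 1L])
  }, 0)
  lex <- vapply(sets, function(db) paste(sprintf("%02d", db), collapse = ","), "")
  nb <- lengths(sets)
  ord <- order(-scores, nb, lex)
  best <- ord[1L]
  if (scores[best] < floor) {
    abort(sprintf(
      "uninterpretable spectrum: best candidate scores %.2f (< %.2f).",
      scores[best], floor), class = "pufapath_spectrum_error")
  }
  cand <- tibble(
    positions = ifelse(nzchar(lex[ord]), gsub("(^|,)0", "\\1", lex[ord]), "none"),
    n_bonds = nb[ord], score = scores[ord])
  structure(
    list(fa = fatty_acid(chain_length, sets[[best]]), score = scores[best],
         chain_length = chain_length, candidates = cand),
    class = "dmox_inference")
}

#' @export
print.dmox_inference <- function(x, ...) {
  cat(sprintf("<dmox_inference> %s  score %.3f (chain %d)\n",
              fa_to_delta(x$fa), x$score, x$chain_length))
  invisible(x)
}

#' @export
tidy.dmox_inference <- function(x, n = 10, ...) head(x$candidates, n)

#' @export
glance.dmox_inference <- function(x, ...) {
  tibble(fa = fa_to_delta(x$fa), n_bonds = length(x$fa$db),
         score = x$score, chain_length = x$chain_length,
         n_candidates = nrow(x$candidates))
}

#' Read and write DMOX spectra
#'
#' Two-column CSV with `mz` and `intensity`; `write_msp()` emits a minimal
#' MSP-style text block.
#'
#' @param path file path.
#' @return `read_spectrum()`: a tibble with columns `mz`, `intensity`.
#' @export
read_spectrum <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE)
  if (!"mz" %in% names(t)) abort_input("spectrum CSV needs an `mz` column.")
  if (!"intensity" %in% names(t)) t$intensity <- 1
  if (any(t$mz <= 0) || anyDuplicated(t$mz)) {
    abort_input("spectrum m/z values must be positive and unique.")
  }
  t[, c("mz", "intensity")]
}

#' @rdname read_spectrum
#' @param spectrum a tibble with columns `mz`, `intensity`.
#' @param name compound name for the block header.
#' @export
write_msp <- function(spectrum, path, name = "unknown") {
  lines <- c(
    sprintf("NAME: %s", name),
    sprintf("Num Peaks: %d", nrow(spectrum)),
    sprintf("%d %g", as.integer(spectrum$mz), spectrum$intensity),
    "")
  writeLines(lines, path)
  invisible(spectrum)
}
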