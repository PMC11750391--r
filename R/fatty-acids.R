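#' Fatty-acid structures and shorthand nomenclature
#'
#' A fatty acid is modelled as a chain length (carbons, with the carboxyl
#' carbon as C1) and a strictly increasing set of double-bond positions in
#' delta notation, where position d denotes a C=C between carbons d and d+1.
#' All bonds are treated as cis; geometry is not modelled. Two shorthand
#' dialects are understood:
#'
#' * the omega dialect `"C:Dn-x"` (e.g. `"20:4n-6"`), where x counts the
#'   terminal double bond from the methyl end and the D bonds are
#'   methylene-interrupted (delta spacing of 3), so the positions expand to
#'   `C - x - 3k` for `k = 0, ..., D-1`;
#' * the delta dialect `"C:D^Δa,b,...^"` (e.g. `"20:2^Δ5,11^"`), which lists
#'   positions explicitly and is the only valid name for
#'   non-methylene-interrupted (NMI) fatty acids.
#'
#' Both the GREEK CAPITAL DELTA (U+0394) and the INCREMENT sign (U+2206) are
#' accepted on input and normalised; the caret markers are optional.
#'
#' @param chain integer chain length (>= 2).
#' @param positions integer vector of delta double-bond positions; each must
#'   lie in `[2, chain - 1]`, and adjacent positions must differ by at least 2
#'   (no cumulated double bonds).
#' @return `fatty_acid()` returns an object of class `"fatty_acid"`.
#' @examples
#' fatty_acid(20, c(5, 11))
#' fa_parse("20:4n-6")
#' @export
fatty_acid <- function(chain, positions = integer()) {
  chain <- as.integer(chain)
  db <- sort(unique(as.integer(positions)))
  if (length(db) != length(positions)) {
    abort_input("duplicate double-bond positions are not allowed.")
  }
  if (is.na(chain) || chain < 2L) {
    abort_input("`chain` must be an integer >= 2.")
  }
  if (length(db) && (any(db < 2L) || any(db > chain - 1L))) {
    abort_input(sprintf(
      "double-bond positions must lie in [2, %d] for an %d-carbon chain.",
      chain - 1L, chain))
  }
  if (length(db) > 1L && any(diff(db) < 2L)) {
    abort_input("adjacent double-bond positions must differ by at least 2.")
  }
  structure(list(chain = chain, db = db), class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat("<fatty_acid> ", fa_to_delta(x), "  (", fa_class(x), ")\n", sep = "")
  invisible(x)
}

#' @export
format.fatty_acid <- function(x, ...) fa_to_delta(x)

#' @export
#' @rdname fatty_acid
#' @param x a `fatty_acid`, or a character shorthand in either dialect.
as_fatty_acid <- function(x) {
  if (inherits(x, "fatty_acid")) return(x)
  if (is.character(x) && length(x) == 1L) return(fa_parse(x))
  abort_input("cannot interpret input as a fatty acid.")
}

#' @export
#' @rdname fatty_acid
fa_chain <- function(x) as_fatty_acid(x)$chain

#' @export
#' @rdname fatty_acid
fa_positions <- function(x) as_fatty_acid(x)$db

# strip carets, unify the two delta glyphs, drop whitespace
normalise_shorthand <- function(text) {
  text <- gsub("∆", "Δ", text, fixed = TRUE)
  text <- gsub("[\\^[:space:]]", "", text)
  text
}

#' Parse fatty-acid shorthand
#'
#' @param text a single shorthand string in the omega dialect (`"20:4n-6"`),
#'   the delta dialect (`"20:2^Δ5,11^"`), or the saturated form (`"18:0"`).
#' @return a [fatty_acid()].
#' @examples
#' fa_parse("20:2^Δ5,11^")
#' @export
fa_parse <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort_parse("`text` must be a single shorthand string.")
  }
  s <- normalise_shorthand(text)
  if (grepl("^\\d+:0$", s)) {
    chain <- as.integer(sub(":0$", "", s))
    return(fatty_acid(chain))
  }
  m <- regmatches(s, regexec("^(\\d+):(\\d+)n-(\\d+)$", s))[[1]]
  if (length(m)) {
    chain <- as.integer(m[2]); d <- as.integer(m[3]); x <- as.integer(m[4])
    if (d < 1L) abort_parse(sprintf("malformed omega shorthand: '%s'", text))
    pos <- chain - x - 3L * (seq_len(d) - 1L)
    if (any(pos < 2L)) {
      abort_parse(sprintf(
        "omega expansion of '%s' yields a double-bond position below C2.", text))
    }
    return(fatty_acid(chain, sort(pos)))
  }
  m <- regmatches(s, regexec("^(\\d+):(\\d+)Δ(\\d+(,\\d+)*)$", s))[[1]]
  if (length(m)) {
    chain <- as.integer(m[2]); d <- as.integer(m[3])
    pos <- as.integer(strsplit(m[4], ",", fixed = TRUE)[[1]])
    if (length(pos) != d) {
      abort_parse(sprintf(
        "'%s' declares %d double bonds but lists %d positions.",
        text, d, length(pos)))
    }
    if (is.unsorted(pos, strictly = TRUE)) {
      abort_parse(sprintf("positions in '%s' must be strictly increasing.", text))
    }
    return(fatty_acid(chain, pos))
  }
  abort_parse(sprintf("cannot parse fatty-acid shorthand: '%s'", text))
}

#' Render a fatty acid in delta notation
#'
#' The canonical delta-dialect name, e.g. `"20:2^Δ5,11^"`; saturated acids
#' render as `"C:0"`. Inverse of [fa_parse()] on its own output.
#'
#' @param x a `fatty_acid` or shorthand string (vectorised over character).
#' @return character.
#' @export
fa_to_delta <- function(x) {
  if (is.character(x) && length(x) > 1L) return(vapply(x, fa_to_delta, "", USE.NAMES = FALSE))
  fa <- as_fatty_acid(x)
  if (!length(fa$db)) return(sprintf("%d:0", fa$chain))
  sprintf("%d:%d^Δ%s^", fa$chain, length(fa$db),
          paste(fa$db, collapse = ","))
}

#' Render a fatty acid in omega (n-x) notation
#'
#' Only saturated, monounsaturated and methylene-interrupted structures have
#' an omega name, with `x = chain - max(positions)`; NMI structures are
#' refused rather than guessed, since the omega dialect cannot encode their
#' spacing.
#'
#' @inheritParams fa_to_delta
#' @return character, e.g. `"20:5n-3"`; saturated acids render as `"C:0"`.
#' @export
fa_to_omega <- function(x) {
  if (is.character(x) && length(x) > 1L) return(vapply(x, fa_to_omega, "", USE.NAMES = FALSE))
  fa <- as_fatty_acid(x)
  cls <- fa_class(fa)
  if (cls == "nmi") {
    abort(sprintf(
      "%s is non-methylene-interrupted and has no omega name; use fa_to_delta().",
      fa_to_delta(fa)), class = "pufapath_omega_error")
  }
  if (!length(fa$db)) return(sprintf("%d:0", fa$chain))
  sprintf("%d:%dn-%d", fa$chain, length(fa$db), fa$chain - max(fa$db))
}

#' Classify the unsaturation pattern of a fatty acid
#'
#' @inheritParams fa_to_delta
#' @return one of `"saturated"`, `"monounsaturated"`,
#'   `"methylene_interrupted"` (>= 2 bonds, every adjacent delta spacing
#'   exactly 3) or `"nmi"` (>= 2 bonds, at least one spacing != 3).
#' @examples
#' fa_class("20:2^Δ5,11^")  # "nmi"
#' fa_class("20:4n-6")           # "methylene_interrupted"
#' @export
fa_class <- function(x) {
  if (is.character(x) && length(x) > 1L) return(vapply(x, fa_class, "", USE.NAMES = FALSE))
  fa <- as_fatty_acid(x)
  nd <- length(fa$db)
  if (nd == 0L) return("saturated")
  if (nd == 1L) return("monounsaturated")
  if (all(diff(fa$db) == 3L)) "methylene_interrupted" else "nmi"
}

#' Summarise fatty-acid shorthand as a tibble
#'
#' Convenience wrapper that parses a character vector of shorthand names and
#' returns one row per acid with its structure and classification, for use in
#' pipelines.
#'
#' @param x character vector of shorthand names (either dialect).
#' @return a tibble with columns `shorthand`, `chain`, `n_double_bonds`,
#'   `positions` (list column), `class`, `delta`, and `omega` (`NA` for NMI
#'   structures).
#' @examples
#' fa_describe(c("20:4n-6", "20:2^Δ5,11^", "18:0"))
#' @export
fa_describe <- function(x) {
  fas <- map(x, fa_parse)
  tibble(
    shorthand = x,
    chain = map_int(fas, "chain"),
    n_double_bonds = map_int(fas, ~ length(.x$db)),
    positions = map(fas, "db"),
    class = map_chr(fas, fa_class),
    delta = map_chr(fas, fa_to_delta),
    omega = map_chr(fas, function(fa) {
      tryCatch(fa_to_omega(fa), pufapath_omega_error = function(e) NA_character_)
    })
  )
}
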