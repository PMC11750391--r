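#' Elongation reaction operator
#'
#' Models the Elovl-catalysed condensation step: a C2 unit is added at the
#' carboxyl end, so the chain grows by 2 and every delta double-bond position
#' shifts by +2 (the omega / n-x class is preserved).
#'
#' @param x a `fatty_acid` or shorthand string.
#' @param cap maximum permitted product chain length. Defaults to 24, the
#'   longest product observed across the packaged enzyme panels.
#' @return a [fatty_acid()].
#' @examples
#' fa_to_omega(elongate("18:3n-3"))  # "20:3n-3"
#' @export
elongate <- function(x, cap = 24L) {
  fa <- as_fatty_acid(x)
  if (fa$chain + 2L > cap) {
    abort_input(sprintf(
      "elongation of %s exceeds the chain-length cap of %d.",
      fa_to_delta(fa), cap))
  }
  fatty_acid(fa$chain + 2L, fa$db + 2L)
}

#' Front-end desaturation reaction operator
#'
#' Models Fads-catalysed insertion of a double bond at delta position `d`
#' (between carbons d and d+1), towards the carboxyl end of any pre-existing
#' unsaturation. The chain length is unchanged.
#'
#' @inheritParams elongate
#' @param d delta position of the new double bond.
#' @return a [fatty_acid()].
#' @examples
#' fa_to_delta(desaturate("20:1n-9", 5))  # "20:2^Δ5,11^"
#' @export
desaturate <- function(x, d) {
  fa <- as_fatty_acid(x)
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d)) abort_input("`d` must be a single position.")
  if (d %in% fa$db) {
    abort_input(sprintf("%s already has a double bond at Δ%d.",
                        fa_to_delta(fa), d))
  }
  if (length(fa$db) && any(abs(fa$db - d) < 2L)) {
    abort_input(sprintf(
      "Δ%d would be cumulated with an existing double bond in %s.",
      d, fa_to_delta(fa)))
  }
  if (d < 2L || d > fa$chain - 1L) {
    abort_input(sprintf("Δ%d is outside the chain of %s.", d, fa_to_delta(fa)))
  }
  fatty_acid(fa$chain, c(fa$db, d))
}

delta_from_label <- function(label) {
  m <- regmatches(label, regexec("^Δ(\\d+)$", normalise_shorthand(label)))[[1]]
  if (!length(m)) return(NA_integer_)
  as.integer(m[2])
}

#' Load the packaged enzyme-activity panels
#'
#' Reads the packaged table of substrate-to-product conversions measured for
#' the 16 sea-urchin enzymes (8 S/MUFA-subfamily elongases, 5 PUFA-subfamily
#' elongases and 3 front-end desaturases) heterologously expressed in yeast.
#' Each quantified row carries the GC conversion percentage; rows below the
#' detection limit are flagged `not_detected` (distinct from a measured zero)
#' and activities documented only on chromatograms (yeast endogenous MUFA
#' elongation; the Δ5 product of 18:0) are flagged `qualitative`.
#'
#' On load every row is validated against the reaction operators: an
#' elongase row's product must equal [elongate()] of its substrate and a
#' desaturase row's product must equal [desaturate()] of its substrate at the
#' position named in `activity_label`.
#'
#' @param path path to a panel CSV; defaults to the packaged fixture.
#' @return a tibble with columns `enzyme`, `kind` (`"elongase"` /
#'   `"desaturase"`), `substrate`, `product` (shorthand as published),
#'   `substrate_delta`, `product_delta` (canonical delta names), `conversion`
#'   (numeric percent, `NA` unless quantified), `status` (`"quantified"`,
#'   `"not_detected"`, `"qualitative"`) and `activity_label`.
#' @examples
#' panels <- load_activity_panels()
#' dplyr::count(panels, kind, status)
#' @export
load_activity_panels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "activity_panels.csv",
                                package = "pufapath", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(encoding = "UTF-8"))
  need <- c("enzyme", "kind", "substrate", "product", "conversion",
            "activity_label")
  if (!all(need %in% names(raw))) {
    abort_input(paste("panel CSV must have columns:", paste(need, collapse = ", ")))
  }
  conv_raw <- as.character(raw$conversion)
  status <- dplyr::case_when(
    conv_raw %in% c("n.d.", "nd", "ND") ~ "not_detected",
    conv_raw %in% c("qual", "qualitative") ~ "qualitative",
    TRUE ~ "quantified"
  )
  conversion <- ifelse(status == "quantified", suppressWarnings(as.numeric(conv_raw)), NA_real_)
  if (any(status == "quantified" & (is.na(conversion) | conversion < 0 | conversion > 100))) {
    abort_input("quantified conversions must be numbers in [0, 100].")
  }
  out <- tibble(
    enzyme = raw$enzyme,
    kind = raw$kind,
    substrate = raw$substrate,
    product = raw$product,
    substrate_delta = fa_to_delta(raw$substrate),
    product_delta = fa_to_delta(raw$product),
    conversion = conversion,
    status = status,
    activity_label = raw$activity_label
  )
  validate_panels(out)
  out
}

# machine-check: every row's product equals the operator applied to its substrate
validate_panels <- function(panels) {
  bad <- character()
  for (i in seq_len(nrow(panels))) {
    sub <- fa_parse(panels$substrate[i])
    expected <- if (panels$kind[i] == "elongase") {
      elongate(sub)
    } else if (panels$kind[i] == "desaturase") {
      d <- delta_from_label(panels$activity_label[i])
      if (is.na(d)) {
        bad <- c(bad, sprintf("row %d: desaturase row without a Δ label", i))
        next
      }
      desaturate(sub, d)
    } else {
      bad <- c(bad, sprintf("row %d: unknown enzyme kind '%s'", i, panels$kind[i]))
      next
    }
    if (!identical(fa_to_delta(expected), panels$product_delta[i])) {
      bad <- c(bad, sprintf(
        "row %d (%s): product %s does not equal operator applied to %s",
        i, panels$enzyme[i], panels$product[i], panels$substrate[i]))
    }
  }
  if (length(bad)) {
    abort(paste0("activity panel failed structural validation:\n",
                 paste(" -", bad, collapse = "\n")),
          class = "pufapath_panel_error")
  }
  invisible(panels)
}
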