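#' Conversion percentage from FAME peak areas
#'
#' The enzyme conversion statistic used with GC-FID peak-area tables:
#' \deqn{100 \times \frac{\sum \mathrm{product\ areas}}
#'       {\mathrm{substrate\ area} + \sum \mathrm{product\ areas}}}
#' Areas are unitless detector responses; no response-factor correction is
#' applied. An all-zero denominator signals a failed assay and raises an
#' error rather than returning 0.
#'
#' `conversion_pct()` is the scalar form; `gc_conversion()` applies it per
#' sample to a tidy peak table.
#'
#' @param substrate_area non-negative substrate peak area.
#' @param product_areas numeric vector of non-negative product peak areas.
#' @return percent in `[0, 100]`.
#' @examples
#' conversion_pct(70, 30)        # 30
#' conversion_pct(50, c(25, 25)) # 50
#' @export
conversion_pct <- function(substrate_area, product_areas) {
  if (length(substrate_area) != 1L || substrate_area < 0 ||
      any(product_areas < 0)) {
    abort_input("peak areas must be non-negative; one substrate area expected.")
  }
  denom <- substrate_area + sum(product_areas)
  if (denom <= 0) {
    abort("substrate and product areas are all zero: assay failed.",
          class = "pufapath_assay_error")
  }
  100 * sum(product_areas) / denom
}

#' @rdname conversion_pct
#' @param peaks a tidy peak table: tibble with columns `sample_id`,
#'   `fatty_acid` (shorthand) and `area`. A single-sample table may omit
#'   `sample_id`.
#' @param substrate shorthand of the substrate fatty acid.
#' @param products character vector of product shorthand names. All named
#'   acids must appear in the table (an undetected product is a 0-area row,
#'   not a missing one).
#' @return `gc_conversion()` returns a tibble with columns `sample_id`,
#'   `substrate` and `conversion`.
#' @export
gc_conversion <- function(peaks, substrate, products) {
  peaks <- as_tibble(peaks)
  if (!"sample_id" %in% names(peaks)) peaks$sample_id <- "sample"
  if (!all(c("fatty_acid", "area") %in% names(peaks))) {
    abort_input("`peaks` needs columns fatty_acid and area.")
  }
  peaks$fa_id <- fa_to_delta(peaks$fatty_acid)
  sub_id <- fa_to_delta(substrate)
  prod_ids <- fa_to_delta(products)
  out <- peaks |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      missing <- setdiff(c(sub_id, prod_ids), d$fa_id)
      if (length(missing)) {
        abort_input(sprintf(
          "sample '%s' lacks peaks for: %s", key$sample_id,
          paste(missing, collapse = ", ")))
      }
      tibble(
        substrate = substrate,
        conversion = conversion_pct(
          sum(d$area[d$fa_id == sub_id]),
          vapply(prod_ids, function(p) sum(d$area[d$fa_id == p]), 0)))
    }) |>
    ungroup()
  out
}

#' Direct and iterated elongation products of a substrate
#'
#' Elongases act processively in the yeast assay: the +C2 product of one step
#' can itself be elongated, so all downstream products count towards the
#' substrate's conversion (e.g. 16:1n-7 yields both 18:1n-7 and 20:1n-7).
#' This chases the given enzyme's panel records from the substrate and
#' returns every cascade product, optionally restricted to acids present in
#' a peak table. Desaturases are single-step by construction and return an
#' empty product list here.
#'
#' @param substrate shorthand of the fed substrate.
#' @param enzyme enzyme name as it appears in `panels`.
#' @param panels activity panels from [load_activity_panels()].
#' @param peaks optional peak table; if given, only products whose shorthand
#'   appears in `peaks$fatty_acid` are returned.
#' @return character vector of product shorthand names in cascade order.
#' @examples
#' multi_step_products("16:1n-7", "Elovl6-like C")
#' @export
multi_step_products <- function(substrate, enzyme,
                                panels = load_activity_panels(),
                                peaks = NULL) {
  rows <- panels[panels$enzyme == enzyme, , drop = FALSE]
  if (!nrow(rows)) abort_input(sprintf("unknown enzyme '%s'.", enzyme))
  if (all(rows$kind == "desaturase")) return(character())
  rows <- rows[rows$status != "not_detected", , drop = FALSE]
  out <- character()
  cur <- fa_to_delta(substrate)
  repeat {
    nxt <- rows[rows$substrate_delta == cur, , drop = FALSE]
    if (!nrow(nxt)) break
    out <- c(out, nxt$product[1L])
    cur <- nxt$product_delta[1L]
  }
  if (!is.null(peaks)) {
    present <- fa_to_delta(unique(peaks$fatty_acid))
    out <- out[fa_to_delta(out) %in% present]
  }
  out
}

#' Read peak-table and assay-specification CSV files
#'
#' `read_peak_table()` expects columns `sample_id`, `fatty_acid`, `area`;
#' `read_assays()` expects `sample_id`, `substrate`, `products` with products
#' separated by `";"`. `gc_conversions()` joins the two and computes the
#' conversion statistic per assay row.
#'
#' @param path CSV file path.
#' @return tibbles; `gc_conversions()` returns one row per assay with
#'   `sample_id`, `substrate`, `conversion`.
#' @export
read_peak_table <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE,
                       locale = readr::locale(encoding = "UTF-8"))
  if (!all(c("sample_id", "fatty_acid", "area") %in% names(t))) {
    abort_input("peak CSV needs columns sample_id, fatty_acid, area.")
  }
  if (any(t$area < 0)) abort_input("peak areas must be non-negative.")
  t
}

#' @rdname read_peak_table
#' @export
read_assays <- function(path) {
  t <- readr::read_csv(path, show_col_types = FALSE,
                       locale = readr::locale(encoding = "UTF-8"))
  if (!all(c("sample_id", "substrate", "products") %in% names(t))) {
    abort_input("assay CSV needs columns sample_id, substrate, products.")
  }
  t
}

#' @rdname read_peak_table
#' @param peaks a peak table from [read_peak_table()].
#' @param assays an assay table from [read_assays()].
#' @export
gc_conversions <- function(peaks, assays) {
  bind_rows(lapply(seq_len(nrow(assays)), function(i) {
    a <- assays[i, ]
    prods <- strsplit(a$products, ";", fixed = TRUE)[[1]]
    prods <- trimws(prods[nzchar(trimws(prods))])
    gc_conversion(peaks[peaks$sample_id == a$sample_id, , drop = FALSE],
                  a$substrate, prods)
  }))
}
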