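#' Simulate motif-bearing protein sequences
#'
#' Generates synthetic amino-acid sequences with the statistical structure
#' the motif screen assumes: a uniform-random 20-letter background with the
#' target class's motif instance(s) embedded at random positions. Rejection
#' sampling guarantees that the classifier returns exactly the requested
#' label with `ambiguous = FALSE` (for `"unclassified"`, that no pattern
#' matches at all), so generator and classifier agree by construction.
#'
#' @param class one of `"smufa_elovl"`, `"pufa_elovl"`, `"fads_like"`,
#'   `"unclassified"`.
#' @param length sequence length in residues.
#' @param seed integer seed (the caller's RNG state is untouched).
#' @param max_tries rejection-sampling budget.
#' @return `sim_protein()`: a single sequence string.
#' @examples
#' sim_protein("smufa_elovl", seed = 1)
#' @export
sim_protein <- function(class = c("smufa_elovl", "pufa_elovl", "fads_like",
                                  "unclassified"),
                        length = 300L, seed = NULL, max_tries = 200L) {
  class <- match.arg(class)
  local_seed(seed, {
    for (i in seq_len(max_tries)) {
      s <- draw_protein_once(class, length)
      lab <- classify_proteins(tibble(id = "x", seq = s))
      if (lab$label == class && !lab$ambiguous) return(s)
    }
    abort("rejection-sampling budget exceeded; increase `length` or `max_tries`.",
          class = "pufapath_sim_error")
  })
}

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# draw one concrete residue string realising a motif pattern
realise_motif <- function(pattern) {
  sets <- parse_motif(pattern)
  paste(vapply(sets, function(s) {
    if (is.null(s)) sample(aa20, 1L) else sample(s, 1L)[[1]]
  }, ""), collapse = "")
}

embed_at <- function(seq, insert, start) {
  paste0(substr(seq, 1L, start - 1L), insert,
         substr(seq, start + nchar(insert), nchar(seq)))
}

draw_protein_once <- function(class, length) {
  pats <- motif_patterns()
  s <- random_aa(length)
  if (class == "unclassified") return(s)
  if (class == "fads_like") {
    # three boxes in N->C order in disjoint thirds of the sequence
    width <- length %/% 3L
    for (b in 1:3) {
      motif <- realise_motif(pats[[paste0("fads_box", b)]])
      lo <- (b - 1L) * width + 1L
      hi <- b * width - nchar(motif)
      s <- embed_at(s, motif, sample(lo:hi, 1L))
    }
    return(s)
  }
  motif <- realise_motif(pats[[class]])
  embed_at(s, motif, sample(seq_len(length - nchar(motif)), 1L))
}

#' Simulate a labelled protein panel
#'
#' A synthetic stand-in for a set of cloned enzyme candidates: `n_smufa` +
#' `n_pufa` + `n_fads` (+ `n_unclassified`) sequences with known true class,
#' ids prefixed `"synthetic_"`.
#'
#' @param n_smufa,n_pufa,n_fads,n_unclassified panel composition; defaults
#'   mirror the packaged enzyme complement (8 S/MUFA Elovl, 5 PUFA Elovl,
#'   3 Fads).
#' @inheritParams sim_protein
#' @return a tibble with columns `id`, `seq`, `true_class`.
#' @examples
#' panel <- sim_protein_panel(seed = 1)
#' dplyr::count(panel, true_class)
#' @export
sim_protein_panel <- function(n_smufa = 8L, n_pufa = 5L, n_fads = 3L,
                              n_unclassified = 0L, length = 300L,
                              seed = NULL) {
  local_seed(seed, {
    spec <- c(smufa_elovl = n_smufa, pufa_elovl = n_pufa,
              fads_like = n_fads, unclassified = n_unclassified)
    rows <- list()
    for (cls in names(spec)) {
      for (k in seq_len(spec[[cls]])) {
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("synthetic_%s_%02d", cls, k),
          seq = sim_protein(cls, length = length),
          true_class = cls)
      }
    }
    bind_rows(rows)
  })
}

#' Simulate a FAME peak-area table with known true conversion
#'
#' Areas are drawn so that the expected product share equals
#' `true_conversion` percent, with independent log-normal multiplicative
#' noise of coefficient of variation `noise_cv` on every area (areas are
#' positive and detector noise is multiplicative). The substrate receives
#' `(100 - p)` area units and the products split `p` equally, all scaled by
#' `scale`. Yeast endogenous background FAMEs (16:0, 16:1n-7, 18:0,
#' 18:1n-9) are added unless they collide with the assay acids.
#'
#' @param substrate,products fatty-acid shorthand names.
#' @param true_conversion target conversion percent in `[0, 100]`.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicate samples (`sample_id` `"rep1"`...).
#' @param scale total substrate-plus-product area in arbitrary units.
#' @param background add endogenous FAME peaks?
#' @inheritParams sim_protein
#' @return a tidy peak table: tibble with `sample_id`, `fatty_acid`, `area`.
#' @examples
#' t <- sim_peak_table("18:2n-6", "20:2n-6", 48, noise_cv = 0, seed = 1)
#' gc_conversion(t, "18:2n-6", "20:2n-6")
#' @export
sim_peak_table <- function(substrate, products, true_conversion,
                           noise_cv = 0.1, n_replicates = 1L,
                           scale = 1000, background = TRUE, seed = NULL) {
  if (true_conversion < 0 || true_conversion > 100) {
    abort_input("`true_conversion` must be in [0, 100].")
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) {
    if (noise_cv == 0) rep(1, n) else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  bg <- c("16:0" = 400, "16:1n-7" = 900, "18:0" = 150, "18:1n-9" = 700)
  assay_ids <- fa_to_delta(c(substrate, products))
  bg <- bg[!fa_to_delta(names(bg)) %in% assay_ids]
  p <- true_conversion / 100
  local_seed(seed, {
    bind_rows(lapply(seq_len(n_replicates), function(r) {
      areas <- c(
        setNames(scale * (1 - p) * noise(1L), substrate),
        setNames(scale * p / max(length(products), 1L) *
                   (if (p > 0) noise(length(products)) else rep(0, length(products))),
                 products),
        if (background) bg * noise(length(bg)))
      tibble(sample_id = sprintf("rep%d", r),
             fatty_acid = names(areas), area = unname(areas))
    }))
  })
}

#' Simulate a noisy DMOX spectrum with known structure
#'
#' Starts from the predicted peak set of `fa` (fragment series, diagnostic
#' ions, molecular ion) with intensities decreasing along the series, then
#' applies seeded peak dropout and adds uniform-random noise peaks. The
#' diagnostic region is protected from dropout: the molecular ion, any
#' diagnostic ion, and both peaks flanking every 12-a.m.u. gap are always
#' kept, so the double-bond evidence is never silently erased. Noise peaks
#' are kept at least 2 m/z away from every true peak so the ground truth
#' stays unambiguous at unit-mass resolution.
#'
#' @param fa a `fatty_acid` or shorthand string.
#' @param n_noise_peaks number of spurious peaks to add.
#' @param dropout_rate per-peak dropout probability outside the protected
#'   region.
#' @inheritParams sim_protein
#' @return a tibble with columns `mz`, `intensity`; attribute `"truth"`
#'   holds the canonical delta name of `fa`.
#' @examples
#' s <- sim_dmox_spectrum("20:2^Δ5,13^", seed = 7)
#' infer_double_bonds(s, 20)
#' @export
sim_dmox_spectrum <- function(fa, n_noise_peaks = 10L, dropout_rate = 0.1,
                              seed = NULL) {
  fa <- as_fatty_acid(fa)
  series <- predict_dmox(fa)
  diag <- diagnostic_ions(fa)
  mol <- molecular_ion(series)
  gap12 <- which(diff(series$mz) == 12L)  # protect both flanks of each gap
  protected_idx <- unique(c(gap12, gap12 + 1L))
  true_mz <- c(series$mz, diag$mz, mol)
  intensity <- c(100 * 0.95^(seq_len(nrow(series)) - 1L),
                 rep(60, nrow(diag)), 40)
  keep <- rep(TRUE, length(true_mz))
  local_seed(seed, {
    droppable <- setdiff(seq_len(nrow(series)), protected_idx)
    keep[droppable] <- runif(length(droppable)) >= dropout_rate
    mz <- true_mz[keep]
    intensity <- intensity[keep]
    if (n_noise_peaks > 0L) {
      pool <- setdiff(100:(mol + 50L),
                      as.vector(outer(true_mz, -1:1, `+`)))
      noise_mz <- sample(pool, n_noise_peaks)
      mz <- c(mz, noise_mz)
      intensity <- c(intensity, runif(n_noise_peaks, 1, 20))
    }
    ord <- order(mz)
    out <- tibble(mz = as.integer(mz[ord]),
                  intensity = round(intensity[ord], 3))
    attr(out, "truth") <- fa_to_delta(fa)
    out
  })
}
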