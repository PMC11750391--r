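#' Motif patterns for Elovl and Fads classification
#'
#' Elovl elongases split into two subfamilies by a conserved histidine motif:
#' S/MUFA-preferring Elovl carry `H-[WT]-X-H-H` and PUFA-preferring Elovl
#' carry the longer `[QH]-X-[TS]-X-L-H-X-X-H-H`. Front-end desaturases carry
#' three histidine boxes, `H-X-X-X-H`, `H-X-X-H-H` and `Q-X-X-H-H`, which
#' must occur in that N-to-C order. In this PROSITE-like notation `X` is a
#' wildcard and square brackets list alternative residues at one position.
#'
#' @return `motif_patterns()`: a named list of pattern strings.
#' @export
motif_patterns <- function() {
  list(
    smufa_elovl = "H-[WT]-X-H-H",
    pufa_elovl  = "[QH]-X-[TS]-X-L-H-X-X-H-H",
    fads_box1   = "H-X-X-X-H",
    fads_box2   = "H-X-X-H-H",
    fads_box3   = "Q-X-X-H-H"
  )
}

# parse "H-[WT]-X-H-H" into a list of allowed-residue sets (NULL = wildcard)
parse_motif <- function(pattern) {
  parts <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (length(parts) < 3L) abort_input("motif patterns must have >= 3 positions.")
  sets <- lapply(parts, function(p) {
    if (p == "X") return(NULL)
    p <- gsub("\\[|\\]", "", p)
    strsplit(p, "")[[1]]
  })
  if (all(vapply(sets, is.null, TRUE))) {
    abort_input("motif pattern must have at least one non-wildcard position.")
  }
  sets
}

motif_regex <- function(pattern) {
  sets <- parse_motif(pattern)
  paste(vapply(sets, function(s) {
    if (is.null(s)) "." else if (length(s) == 1L) s
    else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan a protein sequence for a motif
#'
#' Returns every (possibly overlapping) 1-based start position at which the
#' pattern matches. An `X` in the *sequence* (unknown residue) matches only
#' wildcard pattern positions, never a specific residue set.
#'
#' @param seq an amino-acid string (uppercased on input).
#' @param pattern a pattern string such as `"H-[WT]-X-H-H"`.
#' @return integer vector of start positions (possibly empty).
#' @examples
#' scan_motif("AAHTGHHAA", "H-[WT]-X-H-H")  # 3
#' @export
scan_motif <- function(seq, pattern) {
  seq <- toupper(gsub("[[:space:]*]", "", seq))
  if (!nzchar(seq)) abort_input("`seq` must be a non-empty sequence.")
  rx <- sprintf("(?=%s)", motif_regex(pattern))
  hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% sprintf("seq%d", seq_along(proteins))
    proteins <- tibble(id = ids, seq = unname(proteins))
  }
  proteins <- as_tibble(proteins)
  if (!all(c("id", "seq") %in% names(proteins))) {
    abort_input("`proteins` needs columns `id` and `seq`.")
  }
  proteins$seq <- toupper(gsub("[[:space:]*]", "", proteins$seq))
  if (any(!nzchar(proteins$seq))) abort_input("empty protein sequence.")
  proteins
}

#' Classify Elovl candidates by subfamily motif
#'
#' A sequence is `pufa_elovl` if the 10-residue PUFA motif matches anywhere,
#' otherwise `smufa_elovl` if the S/MUFA motif matches, otherwise
#' `unclassified`. A sequence matching both motifs is labelled `pufa_elovl`
#' (the longer, more specific pattern) with `ambiguous = TRUE`.
#'
#' @param proteins a tibble with columns `id` and `seq`, or a (named)
#'   character vector of sequences.
#' @return a tibble with columns `id`, `label`, `ambiguous`, and `matches`
#'   (list column of tibbles with `pattern` and `start`).
#' @examples
#' classify_elovl(c(a = "AAAHWAHHAAA"))
#' @export
classify_elovl <- function(proteins) {
  p <- as_protein_tbl(proteins)
  pats <- motif_patterns()
  rows <- lapply(seq_len(nrow(p)), function(i) {
    hit_p <- scan_motif(p$seq[i], pats$pufa_elovl)
    hit_s <- scan_motif(p$seq[i], pats$smufa_elovl)
    label <- if (length(hit_p)) "pufa_elovl"
             else if (length(hit_s)) "smufa_elovl"
             else "unclassified"
    m <- bind_rows(
      tibble(pattern = character(), start = integer()),
      if (length(hit_p)) tibble(pattern = "pufa_elovl", start = hit_p),
      if (length(hit_s)) tibble(pattern = "smufa_elovl", start = hit_s))
    tibble(id = p$id[i], label = label,
           ambiguous = length(hit_p) > 0 && length(hit_s) > 0,
           matches = list(m))
  })
  bind_rows(rows)
}

#' Classify Fads candidates by the three-histidine-box screen
#'
#' A sequence is `fads_like` if and only if all three histidine boxes match
#' and their first occurrences appear in N-to-C order
#' (`H-X-X-X-H` before `H-X-X-H-H` before `Q-X-X-H-H`); no spacing
#' constraint is imposed.
#'
#' @inheritParams classify_elovl
#' @return a tibble with columns `id`, `label` (`"fads_like"` or
#'   `"unclassified"`), `ambiguous` (always `FALSE`), and `matches`.
#' @export
classify_fads <- function(proteins) {
  p <- as_protein_tbl(proteins)
  pats <- motif_patterns()[c("fads_box1", "fads_box2", "fads_box3")]
  rows <- lapply(seq_len(nrow(p)), function(i) {
    firsts <- vapply(pats, function(pt) {
      h <- scan_motif(p$seq[i], pt)
      if (length(h)) h[1L] else NA_integer_
    }, 0L)
    ok <- !anyNA(firsts) && firsts[1L] < firsts[2L] && firsts[2L] < firsts[3L]
    m <- tibble(pattern = names(pats)[!is.na(firsts)],
                start = firsts[!is.na(firsts)])
    tibble(id = p$id[i], label = if (ok) "fads_like" else "unclassified",
           ambiguous = FALSE, matches = list(m))
  })
  bind_rows(rows)
}

#' Classify a mixed set of candidate sequences
#'
#' Applies the Fads three-box screen first; anything not `fads_like` is then
#' classified by the Elovl subfamily motifs.
#'
#' @inheritParams classify_elovl
#' @return a tibble as in [classify_elovl()], with label levels
#'   `fads_like`, `pufa_elovl`, `smufa_elovl`, `unclassified`.
#' @export
classify_proteins <- function(proteins) {
  fads <- classify_fads(proteins)
  elovl <- classify_elovl(proteins)
  is_fads <- fads$label == "fads_like"
  bind_rows(fads[is_fads, , drop = FALSE],
            elovl[!is_fads, , drop = FALSE])
}

#' Read and write protein FASTA files
#'
#' Thin wrappers over Biostrings FASTA I/O returning/consuming the tidy
#' `(id, seq)` protein tibble used throughout the motif screen.
#'
#' @param path FASTA file path.
#' @return `read_proteins()`: a tibble with columns `id`, `seq`.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(aa)),
         seq = unname(toupper(as.character(aa))))
}

#' @rdname read_proteins
#' @param proteins a tibble with columns `id` and `seq`.
#' @export
write_proteins <- function(proteins, path) {
  p <- as_protein_tbl(proteins)
  aa <- Biostrings::AAStringSet(setNames(p$seq, p$id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(p)
}

#' Write classification results as CSV
#'
#' @param results a classification tibble from [classify_proteins()] or kin.
#' @param path output CSV path.
#' @export
write_classification_csv <- function(results, path) {
  flat <- results |>
    mutate(match_positions = map_chr(.data$matches, function(m) {
      paste(sprintf("%s:%d", m$pattern, m$start), collapse = ";")
    })) |>
    select("id", "label", "ambiguous", "match_positions")
  readr::write_csv(flat, path)
  invisible(flat)
}
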