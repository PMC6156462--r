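#' Construct an ECM gap signature
#'
#' The eight-cysteine motif (ECM) backbone of an nsLTP reads
#' `C X^g1 C X^g2 CC X^g3 C X^inner C X^g4 C X^g5 C`: eight cysteines
#' with five free inter-cysteine gaps plus the small gap inside the CXC
#' triplet (1 residue in every published cotton member).
#'
#' @param g1,g2,g3,g4,g5 Non-negative inter-cysteine gap lengths.
#' @param inner Residue count inside the CXC triplet.
#' @return Object of class `gap_signature`.
#' @export
gap_signature <- function(g1, g2, g3, inner, g4, g5) {
  v <- c(g1 = g1, g2 = g2, g3 = g3, inner = inner, g4 = g4, g5 = g5)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stop("gap lengths must be non-negative integers")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "gap_signature")
}

#' @export
print.gap_signature <- function(x, ...) {
  cat("<gap_signature>", format_pattern(x), "\n")
  invisible(x)
}

#' Total residue span of an ECM backbone
#'
#' @param sig A `gap_signature`.
#' @return `8 + g1 + g2 + g3 + inner + g4 + g5` (residues).
#' @export
motif_span <- function(sig) {
  8L + sig$g1 + sig$g2 + sig$g3 + sig$inner + sig$g4 + sig$g5
}

#' Parse an ECM pattern string
#'
#' Parses the published pattern dialect, e.g.
#' `"C-X9-C-X13-CC19-C-X1C-X21-C-X13-C"`: `CC<c>` is the fused cysteine
#' dyad followed by `c` spacer residues, and `C-X<i>C` is the CXC
#' triplet.  Only this reading yields eight cysteines for every
#' published pattern.
#'
#' @param text Pattern string.
#' @return A [gap_signature()].
#' @export
parse_pattern <- function(text) {
  m <- regexec("^C-X(\\d+)-C-X(\\d+)-CC(\\d+)-C-X(\\d+)C-X(\\d+)-C-X(\\d+)-C$",
               text)[[1L]]
  if (m[[1L]] == -1L) {
    ref <- "C-X<a>-C-X<b>-CC<c>-C-X<i>C-X<d>-C-X<e>-C"
    # locate the first deviation from the grammar for the error message
    ok <- 0L
    for (k in seq_len(nchar(text))) {
      if (!grepl("^C-X\\d", substr(text, 1L, max(k, 4L)))) break
      ok <- k
    }
    stop("ECM pattern does not match grammar ", ref,
         " (near character ", ok + 1L, "): ", text)
  }
  g <- as.integer(regmatches(text, list(m))[[1L]][-1L])
  gap_signature(g[[1L]], g[[2L]], g[[3L]], g[[4L]], g[[5L]], g[[6L]])
}

#' Format a gap signature in the published pattern dialect
#'
#' Inverse of [parse_pattern()]; byte-identical to the published
#' notation, including the fused `CC<c>` and `C-X<i>C` tokens.
#'
#' @param sig A `gap_signature`.
#' @return Pattern string.
#' @export
format_pattern <- function(sig) {
  sprintf("C-X%d-C-X%d-CC%d-C-X%dC-X%d-C-X%d-C",
          sig$g1, sig$g2, sig$g3, sig$inner, sig$g4, sig$g5)
}

#' Scan a mature protein for the eight-cysteine motif
#'
#' Searches the cysteines of a mature protein for a choice of eight that
#' satisfies the ECM backbone constraints: an adjacent CC dyad at slots
#' 3-4 and a CXC triplet at slots 5-6 with `0 <= inner <= max_inner`
#' residues inside.  When several backbones qualify, the match
#' minimizing (number of stray cysteines inside the motif span, then
#' leftmost first cysteine, then lexicographically smallest position
#' vector) is returned.  Scanning is performed on the mature protein
#' only, never the precursor.
#'
#' @param mature Mature-protein amino-acid sequence.
#' @param max_inner Largest allowed CXC inner gap (published cotton
#'   members all show 1; the default keeps other species scannable).
#' @return An object of class `ecm_match` — list with `signature`
#'   (a [gap_signature()]), `cys_positions` (eight 1-based indices into
#'   the mature sequence), `n_extra_cys` — or `NULL` when no backbone
#'   exists.
#' @export
scan_ecm <- function(mature, max_inner = 3L) {
  pos <- which(strsplit(toupper(mature), "")[[1L]] == "C")
  m <- length(pos)
  if (m < 8L) return(NULL)
  best <- NULL
  best_key <- NULL
  consider <- function(p8) {
    n_extra <- sum(pos > p8[[1L]] & pos < p8[[8L]]) - 6L
    key <- c(n_extra, p8)
    if (is.null(best_key) ||
        isTRUE((key - best_key)[which(key != best_key)[1L]] < 0)) {
      best_key <<- key
      best <<- p8
    }
  }
  # structured enumeration: dyad (slots 3-4), CXC (slots 5-6), then the
  # flanking pairs (slots 1-2 and 7-8)
  for (i3 in seq_len(m)) {
    p3 <- pos[[i3]]
    if (!((p3 + 1L) %in% pos)) next            # CC dyad
    before <- pos[pos < p3]
    if (length(before) < 2L) next
    cand5 <- pos[pos > p3 + 1L]
    for (p5 in cand5) {
      cand6 <- pos[pos > p5 & pos <= p5 + max_inner + 1L]
      for (p6 in cand6) {
        after <- pos[pos > p6]
        if (length(after) < 2L) next
        for (a1 in seq_len(length(before) - 1L)) {
          for (a2 in (a1 + 1L):length(before)) {
            for (b1 in seq_len(length(after) - 1L)) {
              for (b2 in (b1 + 1L):length(after)) {
                consider(c(before[[a1]], before[[a2]], p3, p3 + 1L,
                           p5, p6, after[[b1]], after[[b2]]))
              }
            }
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  ecm_match_from_positions(best, pos)
}

# Assemble an ecm_match from eight chosen cysteine positions.
ecm_match_from_positions <- function(p8, all_cys) {
  gaps <- diff(p8) - 1L
  sig <- gap_signature(gaps[[1L]], gaps[[2L]], gaps[[4L]], gaps[[5L]],
                       gaps[[6L]], gaps[[7L]])
  structure(list(
    signature = sig,
    cys_positions = as.integer(p8),
    n_extra_cys = sum(all_cys > p8[[1L]] & all_cys < p8[[8L]]) - 6L
  ), class = "ecm_match")
}

#' @export
print.ecm_match <- function(x, ...) {
  cat("<ecm_match>", format_pattern(x$signature),
      "at", paste(x$cys_positions, collapse = ","),
      sprintf("(%d stray Cys)\n", x$n_extra_cys))
  invisible(x)
}
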