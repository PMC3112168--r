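# Kyte-Doolittle hydropathy scale; hydrophilic residues have values < 0.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Find candidate omega sites
#'
#' GPI anchors attach at an omega residue with a small side chain
#' (G, C, D, A, N or S). This returns every such position within a window
#' from the C-terminus, 1-based on the full-length polypeptide.
#'
#' @param seq a [sequence_record()] or character string.
#' @param search_window number of C-terminal residues scanned (default 40;
#'   canonical motifs sit near the terminus).
#'
#' @return Integer vector of candidate positions (possibly empty).
#' @export
find_omega_candidates <- function(seq, search_window = 40) {
  s <- seq_chars(as_sequence(seq))
  n <- length(s)
  lo <- max(1L, n - search_window + 1L)
  idx <- lo:n
  idx[s[idx] %in% OMEGA_SET]
}

# Longest terminal run: max suffix length whose mean hydropathy meets the
# cutoff (internal dips allowed as long as the suffix mean stays above it).
longest_hydrophobic_suffix <- function(kd, cutoff) {
  n <- length(kd)
  if (n == 0L) return(0L)
  suf_mean <- rev(cumsum(rev(kd))) / rev(seq_len(n))  # mean of kd[i..n]
  lens <- (n - seq_len(n) + 1L)[suf_mean >= cutoff]
  if (length(lens) == 0L) 0L else max(lens)
}

#' Score a candidate omega site against the four GPI-motif elements
#'
#' Evaluates, at a candidate omega position: (a) omega residue small
#' (G/C/D/A/N/S); (b) omega+1..2 small (G/A/S); (c) a hydrophilic spacer --
#' more than 6 residues with hydropathy < 0 within some 7-12 residue window
#' starting at omega+3; (d) a C-terminal hydrophobic stretch -- a terminal
#' run of at least `tail_min` residues with mean hydropathy >= `tail_cutoff`.
#' The composite score is the mean of the four component scores (each capped
#' at 1); classification is `"anchored"` iff all four components pass and the
#' composite reaches `threshold` (mandatory gating prevents score inflation
#' by partial matches).
#'
#' @param seq a [sequence_record()] or character string.
#' @param omega 1-based omega position.
#' @param threshold composite score needed for an "anchored" call.
#' @param tail_cutoff mean-hydropathy cutoff for the hydrophobic tail.
#' @param tail_min minimum hydrophobic tail length, residues.
#' @param spacer_windows window lengths tried for the spacer rule.
#' @param scale named hydropathy scale (default Kyte-Doolittle).
#'
#' @return List of class `gpi_motif_score`: `omega`, `residue`, `components`
#'   (data.frame with `component`, `score`, `pass`), `composite`,
#'   `classification` (`"anchored"` / `"not_anchored"`).
#' @export
score_gpi_motif <- function(seq, omega, threshold = 0.7, tail_cutoff = 1.5,
                            tail_min = 8, spacer_windows = 7:12,
                            scale = KYTE_DOOLITTLE) {
  s <- seq_chars(as_sequence(seq))
  n <- length(s)
  if (omega < 1 || omega > n) stop("omega position out of range")
  kd <- unname(scale[s])
  # (a) small residue at omega
  sc_a <- as.numeric(s[omega] %in% OMEGA_SET)
  # (b) small residues at omega+1, omega+2 (missing residues count as fail)
  om12 <- s[omega + 1:2]
  sc_b <- sum(!is.na(om12) & om12 %in% OMEGA12_SET) / 2
  # (c) hydrophilic spacer from omega+3: best hydrophilic count over windows
  sp_start <- omega + 3L
  best_hydrophilic <- 0L
  if (sp_start <= n) {
    for (wl in spacer_windows) {
      sp_end <- min(n, sp_start + wl - 1L)
      cnt <- sum(kd[sp_start:sp_end] < 0)
      best_hydrophilic <- max(best_hydrophilic, cnt)
    }
  }
  sc_c <- min(1, best_hydrophilic / 7)
  pass_c <- best_hydrophilic > 6
  # (d) terminal hydrophobic stretch, within the region downstream of the
  # omega+1..2 pair (the motif's own tail, not upstream sequence)
  kd_down <- if (sp_start <= n) kd[sp_start:n] else numeric(0)
  run <- longest_hydrophobic_suffix(kd_down, tail_cutoff)
  sc_d <- min(1, run / tail_min)
  pass_d <- run >= tail_min
  comp <- data.frame(
    component = c("omega_small", "omega12_small", "hydrophilic_spacer",
                  "hydrophobic_tail"),
    score = c(sc_a, sc_b, sc_c, sc_d),
    pass = c(sc_a == 1, sc_b == 1, pass_c, pass_d))
  composite <- mean(comp$score)
  anchored <- all(comp$pass) && composite >= threshold
  structure(list(omega = as.integer(omega), residue = s[omega],
                 components = comp, composite = composite,
                 classification = if (anchored) "anchored" else "not_anchored"),
            class = "gpi_motif_score")
}

# Best composite over all omega candidates of a sequence; 0 when none.
best_motif_score <- function(seq, search_window = 40, ...) {
  cands <- find_omega_candidates(seq, search_window)
  if (length(cands) == 0L) {
    return(list(omega = NA_integer_, composite = 0,
                classification = "not_anchored"))
  }
  scores <- lapply(cands, function(om) score_gpi_motif(seq, om, ...))
  comps <- vapply(scores, `[[`, numeric(1), "composite")
  anch <- vapply(scores, function(x) x$classification == "anchored", logical(1))
  # prefer anchored calls, then highest composite, then most C-terminal omega
  ord <- order(!anch, -comps, -cands)
  best <- scores[[ord[1]]]
  list(omega = best$omega, composite = best$composite,
       classification = best$classification, score = best)
}

#' C-terminal truncation scan
#'
#' Recomputes the best composite GPI-motif score over all omega candidates
#' after removing 0, 1, 2, ... residues from the carboxy terminus. Losing the
#' hydrophobic tail (or spacer) makes the score collapse, which localises the
#' motif; a scan over a protein with no motif stays flat near zero.
#'
#' @param seq a [sequence_record()] or character string.
#' @param max_steps number of truncation steps; default down to a minimal
#'   motif span of 12 residues.
#' @param search_window,... passed to [find_omega_candidates()] /
#'   [score_gpi_motif()].
#'
#' @return data.frame of class `truncation_scan` with columns `step`
#'   (residues removed), `length`, `best_omega`, `score`, `anchored`.
#' @export
truncation_scan <- function(seq, max_steps = NULL, search_window = 40, ...) {
  s <- as_sequence(seq)
  n <- nchar(s)
  min_span <- 12L
  if (n < min_span) stop("sequence shorter than the minimal motif span")
  if (is.null(max_steps)) max_steps <- n - min_span
  max_steps <- min(max_steps, n - min_span)
  rows <- lapply(0:max_steps, function(st) {
    sub <- substr(s, 1L, n - st)
    b <- best_motif_score(sub, search_window = search_window, ...)
    data.frame(step = st, length = n - st, best_omega = b$omega,
               score = b$composite, anchored = b$classification == "anchored")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("truncation_scan", "data.frame")
  out
}

#' Classify a panel of sequences
#'
#' Applies the rule-based motif scan to each sequence and reports the best
#' omega candidate and classification. This is a transparent rule-based
#' surrogate for dedicated GPI predictors (Big-PI, FragAnchor, PredGPI): it
#' reproduces qualitative anchored / not-anchored calls, not their numeric
#' scores.
#'
#' @param seqs list of [sequence_record()]s (or a named character vector).
#' @param ... passed to [score_gpi_motif()] / [find_omega_candidates()].
#'
#' @return data.frame with `id`, `omega`, `composite`, `classification`.
#' @export
classify_panel <- function(seqs, ...) {
  stopifnot(length(seqs) >= 1)
  if (is.character(seqs)) {
    ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
    seqs <- Map(sequence_record, ids, seqs)
  }
  rows <- lapply(seqs, function(sr) {
    b <- best_motif_score(sr, ...)
    data.frame(id = sr$id, omega = b$omega, composite = b$composite,
               classification = b$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
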