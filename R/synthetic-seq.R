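# Residue sets used by the generator and the motif rules.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
OMEGA_SET <- c("G", "C", "D", "A", "N", "S")   # small side chains at omega
OMEGA12_SET <- c("G", "A", "S")                # small side chains at omega+1..2
HYDROPHILIC_SET <- c("S","T","N","Q","E","K","D","R","H")  # KD < 0, non-bulky
HYDROPHOBIC_SET <- c("L","I","V","F")          # strong KD > 0, L-rich tails

#' Generate a designed C-terminal test sequence
#'
#' Builds protein sequences whose carboxy termini either satisfy all four
#' elements of a canonical GPI-anchoring motif, or deliberately break it the
#' way a transmembrane-plus-intracellular-tail replacement does:
#'
#' * `"intact_gpi"`: random exofacial head, then omega (small residue),
#'   omega+1..2 small residues, a hydrophilic spacer (>= 7 residues with
#'   Kyte-Doolittle hydropathy < 0 starting at omega+3), and a C-terminal
#'   leucine-rich hydrophobic stretch.
#' * `"disrupted_tail"`: the same head and omega, but everything downstream
#'   replaced by a lysine-containing TM-like segment plus a 17-residue
#'   hydrophilic intracellular tail, emulating swapping the motif for the
#'   transmembrane + intracellular region of an inert type-I reporter.
#' * `"no_motif"`: head plus an all-lysine tail; no omega candidate can
#'   satisfy the spacer and tail rules.
#'
#' @param template one of `"intact_gpi"`, `"disrupted_tail"`, `"no_motif"`.
#' @param head_length length of the upstream (exofacial) region.
#' @param spacer_length hydrophilic spacer length for `"intact_gpi"` (>= 0;
#'   motif-satisfying designs need >= 7).
#' @param tail_length hydrophobic tail length for `"intact_gpi"` (>= 0;
#'   motif-satisfying designs need >= 8).
#' @param id sequence identifier.
#' @param seed integer seed.
#'
#' @return A [sequence_record()]; `regions$omega` gives the designed omega
#'   position (1-based on the full sequence) where applicable.
#' @export
generate_sequences <- function(template = c("intact_gpi", "disrupted_tail",
                                            "no_motif"),
                               head_length = 30, spacer_length = 8,
                               tail_length = 12, id = NULL, seed = NULL) {
  template <- match.arg(template)
  stopifnot(head_length >= 0, spacer_length >= 0, tail_length >= 0)
  if (is.null(id)) id <- template
  gen <- function() {
    head <- paste(sample(setdiff(AA20, c("K")), head_length, replace = TRUE),
                  collapse = "")
    if (template == "intact_gpi") {
      omega <- sample(OMEGA_SET, 1)
      om12 <- paste(sample(OMEGA12_SET, 2, replace = TRUE), collapse = "")
      spacer <- paste(sample(HYDROPHILIC_SET, spacer_length, replace = TRUE),
                      collapse = "")
      tail <- paste(sample(c(rep("L", 4), HYDROPHOBIC_SET), tail_length,
                           replace = TRUE), collapse = "")
      seq <- paste0(head, omega, om12, spacer, tail)
      sequence_record(id, seq, regions = list(omega = nchar(head) + 1L,
                                              template = template))
    } else if (template == "disrupted_tail") {
      omega <- sample(OMEGA_SET, 1)
      # TM-like segment: bulky hydrophobics with interspersed lysines
      tm <- sample(c(rep("L", 8), rep("I", 4), rep("V", 4), rep("F", 3)),
                   19, replace = TRUE)
      kpos <- sample(seq_along(tm), 3)
      tm[kpos] <- "K"
      tail17 <- paste(sample(c("S","T","N","Q","E","K","D","R","G"), 17,
                             replace = TRUE), collapse = "")
      seq <- paste0(head, omega, paste(tm, collapse = ""), tail17)
      sequence_record(id, seq, regions = list(omega = nchar(head) + 1L,
                                              template = template))
    } else {
      seq <- paste0(head, strrep("K", 25))
      sequence_record(id, seq, regions = list(template = template))
    }
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}
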