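test_that("omega candidates are a membership scan over the search window", {
  polyk <- sequence_record("polyK", strrep("K", 50))
  expect_length(find_omega_candidates(polyk), 0)

  s <- sequence_record("x", paste0(strrep("L", 30), "CGGV"))
  cands <- find_omega_candidates(s, search_window = 10)
  expect_true(all(c(31, 32, 33) %in% cands))
  expect_false(34 %in% cands)  # V is not a small residue

  set.seed(20)
  for (i in 1:10) {
    aa <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
    seq <- paste(sample(aa, 80, replace = TRUE), collapse = "")
    got <- find_omega_candidates(seq, search_window = 40)
    ch <- strsplit(seq, "")[[1]]
    brute <- which(ch %in% c("G","C","D","A","N","S") & seq_along(ch) > 40)
    expect_equal(got, brute)
  }
})

test_that("motif scoring enforces all four elements with mandatory gating", {
  intact <- generate_sequences("intact_gpi", seed = 8)
  sc <- score_gpi_motif(intact, intact$regions$omega)
  expect_true(all(sc$components$pass))
  expect_equal(sc$composite, 1)
  expect_equal(sc$classification, "anchored")

  disrupted <- generate_sequences("disrupted_tail", seed = 8)
  sc2 <- score_gpi_motif(disrupted, disrupted$regions$omega)
  fails <- sc2$components[!sc2$components$pass, "component"]
  expect_true(any(c("hydrophilic_spacer", "hydrophobic_tail") %in% fails))
  expect_equal(sc2$classification, "not_anchored")

  # omega at the final residue: spacer and tail components must fail
  endseq <- paste0(strrep("L", 20), "G")
  sc3 <- score_gpi_motif(endseq, 21)
  comp <- sc3$components
  expect_false(comp$pass[comp$component == "hydrophilic_spacer"])
  expect_false(comp$pass[comp$component == "hydrophobic_tail"])
  expect_equal(sc3$classification, "not_anchored")
  expect_error(score_gpi_motif(endseq, 99), "out of range")
})

test_that("weakening a single component never raises the composite", {
  intact <- generate_sequences("intact_gpi", spacer_length = 8,
                               tail_length = 12, seed = 9)
  om <- intact$regions$omega
  full <- score_gpi_motif(intact, om)$composite
  s <- intact$seq
  # shorten the hydrophobic tail below the minimum
  shorter <- substr(s, 1, nchar(s) - 6)
  expect_lte(score_gpi_motif(shorter, om)$composite, full)
  # replace the spacer with hydrophobic residues
  sp_start <- om + 3
  broken <- paste0(substr(s, 1, sp_start - 1), strrep("L", 8),
                   substr(s, sp_start + 8, nchar(s)))
  expect_lte(score_gpi_motif(broken, om)$composite, full)
  # mutate omega+1 to a bulky residue
  bulky <- s
  substr(bulky, om + 1, om + 1) <- "W"
  expect_lte(score_gpi_motif(bulky, om)$composite, full)
})

test_that("classification ignores residues upstream of the search window", {
  tailpart <- generate_sequences("intact_gpi", head_length = 20, seed = 10)
  base <- classify_panel(list(tailpart))
  set.seed(30)
  for (i in 1:5) {
    prefix <- paste(sample(c("K", "W", "P", "E"), 60, replace = TRUE),
                    collapse = "")
    padded <- sequence_record("padded", paste0(prefix, tailpart$seq))
    got <- classify_panel(list(padded))
    expect_equal(got$classification, base$classification)
    expect_equal(got$omega - 60, base$omega)
  }
})

test_that("truncation scans equal independent rescans at every step", {
  intact <- generate_sequences("intact_gpi", seed = 11)
  ts <- truncation_scan(intact, max_steps = 25)
  expect_true(ts$anchored[1])
  # independent rescan of each truncated string
  n <- nchar(intact$seq)
  for (st in ts$step) {
    sub <- substr(intact$seq, 1, n - st)
    cands <- find_omega_candidates(sub)
    best <- if (length(cands) == 0) 0 else
      max(vapply(cands, function(om) score_gpi_motif(sub, om)$composite,
                 numeric(1)))
    expect_equal(ts$score[ts$step == st], best)
  }
  # removing the whole hydrophobic tail (12 residues) kills the motif
  expect_false(ts$anchored[ts$step == 12])
  expect_lt(ts$score[ts$step == 12], ts$score[1])
  # homopolymer: flat trajectory
  ts_g <- truncation_scan(strrep("G", 40), max_steps = 10)
  expect_equal(length(unique(ts_g$score)), 1L)
})

test_that("the rule engine is specific on random sequences", {
  set.seed(77)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  seqs <- vapply(1:1000, function(i) {
    paste(sample(aa, 100, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("rnd", 1:1000)
  cls <- classify_panel(seqs)
  expect_lt(mean(cls$classification == "anchored"), 0.05)
})

test_that("panel classification mirrors the designed construct contrasts", {
  panel <- list(
    generate_sequences("intact_gpi", id = "alpha2delta3_like", seed = 1),
    generate_sequences("disrupted_tail", id = "pin_tmi_like", seed = 1),
    generate_sequences("no_motif", id = "no_tail_control", seed = 1))
  cls <- classify_panel(panel)
  expect_equal(cls$classification,
               c("anchored", "not_anchored", "not_anchored"))
})
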