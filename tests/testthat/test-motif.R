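test_that("the beta-1 tail yields the documented proximal and distal hits", {
  b1 <- optic_tail_fixtures()$ITGB1
  hits <- find_motifs(b1)
  prox <- hits[hits$motif_class == "membrane_proximal", ]
  dist <- hits[hits$motif_class == "membrane_distal", ]
  expect_equal(prox$end, 783)
  expect_equal(prox$terminal_residue, "Y")
  expect_equal(prox$sequence, "NPIY")
  expect_equal(dist$sequence, "NPKY")
  expect_lt(prox$start, dist$start)
})

test_that("Y783A abolishes the membrane-proximal hit", {
  b1 <- optic_tail_fixtures()$ITGB1
  mut <- apply_mutation(b1, "Y783A")
  hits <- find_motifs(mut)
  expect_false("membrane_proximal" %in% hits$motif_class)
  expect_match(mut$name, "Y783A")
})

test_that("mutations validate the reference residue and invert cleanly", {
  b1 <- optic_tail_fixtures()$ITGB1
  identity <- apply_mutation(b1, "Y783Y")
  expect_equal(identity$residues, b1$residues)
  expect_match(identity$name, "Y783Y")
  expect_error(apply_mutation(b1, "W783A"), "mismatch")
  expect_error(apply_mutation(b1, "Y100A"), "outside the tail")
  roundtrip <- apply_mutation(apply_mutation(b1, "Y783A"), "A783Y")
  expect_equal(roundtrip$residues, b1$residues)
})

test_that("motif coordinates shift with the numbering offset", {
  b1 <- optic_tail_fixtures()$ITGB1
  shifted <- tail_sequence(b1$name, b1$residues, start_index = 1L)
  h1 <- find_motifs(b1); h2 <- find_motifs(shifted)
  expect_equal(h1$start - h2$start, rep(761L, nrow(h1)))
  expect_equal(h1$motif_class, h2$motif_class)
})

test_that("every proximal hit also matches the loose Nxx[YF] pattern", {
  for (tl in optic_tail_fixtures()) {
    hits <- find_motifs(tl)
    prox <- hits[hits$motif_class == "membrane_proximal", ]
    if (nrow(prox)) {
      rel <- prox$start - tl$start_index + 1L
      expect_true(rel %in% opticr:::match_starts(tl$residues, "N..[YF]"))
    }
  }
})

test_that("the presence table reproduces the documented motif architecture", {
  tails <- optic_tail_fixtures()
  tab <- motif_presence_table(tails)
  with_prox <- tab$name[tab$membrane_proximal]
  expect_true(all(c("ITGB1", "ITGB2", "ITGB3", "ITGB5", "ITGB6", "ITGB7")
                  %in% with_prox))
  expect_false(tab$membrane_proximal[tab$name == "ITGB8"])
  # the protozoan tails carry the proximal class motif, ITGB2 ending in F
  expect_true(tab$membrane_proximal[tab$name == "ITGB1_Cow"])
  expect_true(tab$membrane_proximal[tab$name == "ITGB2_Cow"])
  expect_equal(tab$proximal_terminal[tab$name == "ITGB2_Cow"], "F")
  # mutating the NPxF phenylalanine to alanine erases the hit
  npxa <- apply_mutation(tails$ITGB2_Cow, "F22A")
  expect_false(any(find_motifs(npxa)$motif_class == "membrane_proximal"))
  # featureless control
  dummy <- tail_sequence("polyA", strrep("A", 30))
  expect_equal(nrow(find_motifs(dummy)), 0)
  expect_false(any(motif_presence_table(list(dummy))$membrane_proximal))
})

test_that("tail sequences validate their alphabet and FASTA round-trips", {
  expect_error(tail_sequence("bad", "NPXY"), "invalid residue")
  expect_error(tail_sequence("bad", ""), "non-empty")
  tails <- optic_tail_fixtures()
  tmp <- tempfile(fileext = ".fa")
  write_tail_fasta(tails, tmp)
  back <- read_tail_fasta(tmp)
  expect_equal(unname(lapply(tails, unclass)), lapply(back, unclass))
})
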