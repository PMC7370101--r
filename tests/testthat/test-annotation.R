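test_that("hydropathy segmentation finds a single hydrophobic block", {
  seqs <- paste0(strrep("D", 30), strrep("L", 30), strrep("D", 30))
  tm <- predict_tm_segments(seqs)
  expect_equal(nrow(tm), 1L)
  # the detected run may lose a few residues to edge effects but must sit
  # inside the leucine block and cover most of it
  expect_gte(tm$start, 30 - 2)
  expect_lte(tm$end, 60 + 2)
  expect_gte(tm$length, 20)
})

test_that("all-polar sequences yield no TM segments and short input errors", {
  expect_equal(nrow(predict_tm_segments(strrep("D", 100))), 0L)
  expect_error(predict_tm_segments("MNPA"), class = "aqpkit_input_error")
})

test_that("templates recover their six planted TM segments", {
  refs <- aqp_reference_set()
  for (r in seq_len(nrow(refs))) {
    tm <- predict_tm_segments(refs$sequence[r])
    planted <- refs$tm[[r]]
    expect_equal(nrow(tm), 6L, info = refs$id[r])
    for (k in 1:6) {
      ov <- min(tm$end[k], planted$end[k]) - max(tm$start[k], planted$start[k])
      expect_gte(ov / (tm$end[k] - tm$start[k]), 0.8)
      expect_gte(ov / (planted$end[k] - planted$start[k]), 0.8)
    }
  }
})

test_that("NPA anchoring returns the loop-B/loop-E pair in order", {
  # canonical PIP-like context strings separated by a plausible loop span
  seqs <- paste0(strrep("G", 40), "SGGHINPAVT", strrep("S", 100),
                 "GTGINPARSLG", strrep("G", 40))
  anch <- find_npa_anchors(seqs)
  expect_equal(anch$loop, c("B", "E"))
  expect_equal(anch$tripeptide, c("NPA", "NPA"))
  expect_lt(anch$n_index[1], anch$n_index[2])

  # SIP-like variant: NPT in loop B, NPA in loop E
  sip <- paste0(strrep("G", 40), "STGHLNPTVT", strrep("S", 100),
                "GASLNPARSLG", strrep("G", 40))
  anch2 <- find_npa_anchors(sip)
  expect_equal(anch2$tripeptide, c("NPT", "NPA"))

  single <- paste0(strrep("G", 50), "NPA", strrep("G", 50))
  expect_error(find_npa_anchors(single), class = "aqpkit_anchor_error")
})

test_that("anchoring is invariant to terminal padding with polar residues", {
  refs <- aqp_reference_set()
  for (r in c(1, 8, 16)) {
    seqs <- refs$sequence[r]
    base <- find_npa_anchors(seqs)
    padded <- find_npa_anchors(paste0(strrep("S", 20), seqs, strrep("S", 20)))
    expect_equal(padded$n_index, base$n_index + 20L)
    expect_equal(padded$tripeptide, base$tripeptide)
  }
})

test_that("the completeness screen passes templates and rejects truncations", {
  refs <- aqp_reference_set()
  verdicts <- screen_proteins(refs[, c("id", "sequence")])
  expect_true(all(verdicts$status == "complete"))
  expect_true(all(lengths(verdicts$reasons) == 0))

  tpl <- refs$sequence[refs$id == "ref_PIP1"]
  short <- tibble::tibble(id = "trunc", sequence = substr(tpl, 1, 120))
  v <- screen_proteins(short)
  expect_equal(v$status, "pseudogene_like")
  expect_true(all(c("length", "npa_anchors") %in% v$reasons[[1]]))

  # surgically remove the loop-E NPA tripeptide
  pos <- aqp_reference_set()$positions[[1]][["NPA2_N"]]
  no_le <- paste0(substr(tpl, 1, pos), substr(tpl, pos + 4, nchar(tpl)))
  v2 <- screen_proteins(tibble::tibble(id = "noLE", sequence = no_le))
  expect_equal(v2$status, "pseudogene_like")
  expect_true("npa_anchors" %in% v2$reasons[[1]])
})

test_that("molecular weight follows residue summation with one water", {
  expect_equal(round(as.numeric(compute_mw("G")), 3), 0.075)
  expect_equal(round(as.numeric(compute_mw("GG")), 3), 0.132)
  expect_true(attr(compute_mw("GXG"), "approximate"))
  expect_false(attr(compute_mw("GAG"), "approximate"))

  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  set.seed(7)
  seqs <- random_protein(300)
  oracle <- (sum(masses[strsplit(seqs, "")[[1]]]) + 18.0153) / 1000
  expect_equal(as.numeric(compute_mw(seqs)), oracle, tolerance = 1e-10)
})

test_that("isoelectric point respects acidic/basic bounds and the grid oracle", {
  expect_lt(compute_pi("DDDDDD"), 4.5)
  expect_gt(compute_pi("KKKKKK"), 9.5)
  set.seed(11)
  for (k in 1:5) {
    seqs <- random_protein(60)
    expect_equal(compute_pi(seqs), oracle_pi_grid(seqs), tolerance = 0.01)
  }
})

test_that("pI is monotone under appending charged residues", {
  set.seed(13)
  for (k in 1:5) {
    seqs <- random_protein(50)
    base <- compute_pi(seqs)
    expect_gte(compute_pi(paste0(seqs, "K")) + 1e-9, base)
    expect_lte(compute_pi(paste0(seqs, "D")) - 1e-9, base)
  }
})
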