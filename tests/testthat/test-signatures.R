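test_that("NPA-region windows reproduce the canonical printed strings", {
  refs <- aqp_reference_set()
  pip <- refs[refs$id == "ref_PIP1", ]
  anch <- find_npa_anchors(pip$sequence,
                           tm = predict_tm_segments(pip$sequence))
  reg <- extract_npa_regions(pip$sequence, anch)
  expect_equal(reg$lb_region, "SGGHINPAVT")
  expect_equal(reg$le_region, "GTGINPARSLG")
  expect_length(reg$flags, 0)

  nip2 <- refs[refs$id == "ref_NIP2", ]
  anch2 <- find_npa_anchors(nip2$sequence,
                            tm = predict_tm_segments(nip2$sequence))
  reg2 <- extract_npa_regions(nip2$sequence, anch2)
  expect_equal(reg2$lb_region, "SGAHMNPAVT")
  expect_equal(reg2$le_region, "GGSMNPARTLG")
})

test_that("a window that leaves the sequence is flagged, not an error", {
  anch <- tibble::tibble(loop = c("B", "E"), n_index = c(2L, 90L),
                         tripeptide = c("NPA", "NPA"))
  reg <- extract_npa_regions(strrep("G", 120), anch)
  expect_true(is.na(reg$lb_region))
  expect_true("position_unresolved:lb_region" %in% reg$flags)
  expect_false(is.na(reg$le_region))
})

test_that("full signatures match the planted template values", {
  refs <- aqp_reference_set()
  for (id in c("ref_PIP1", "ref_TIP2", "ref_NIP2", "ref_SIP1", "ref_XIP1")) {
    tpl <- refs[refs$id == id, ]
    anch <- find_npa_anchors(tpl$sequence,
                             tm = predict_tm_segments(tpl$sequence))
    sig <- extract_signature(tpl$sequence, anch, tpl, id = id)
    expect_equal(sig$arR, tpl$arR, info = id)
    expect_equal(sig$froger, tpl$fp, info = id)
    expect_length(sig$flags[[1]], 0)
  }
  # the PIP filter is the published F-H-T-R; TIP Froger P3-P5 are A, Y, W
  pip <- refs[refs$id == "ref_PIP1", ]
  expect_equal(pip$arR, "FHTR")
  expect_equal(substr(refs$fp[refs$id == "ref_TIP1"], 3, 5), "AYW")
})

test_that("every reported signature residue sits at its reported coordinate", {
  w <- classified_world(0.15, n_per_subfamily = 5L, seed = 8L,
                        with_signatures = TRUE)
  sigs <- w$sigs
  prot <- w$fam$proteins
  for (i in seq_len(nrow(sigs))) {
    seqs <- prot$sequence[prot$id == sigs$id[i]]
    co <- sigs$coords[[i]]
    expect_equal(substr(seqs, co[["NPA1_N"]] + 1, co[["NPA1_N"]] + 1), "N")
    arr <- strsplit(sigs$arR[i], "")[[1]]
    for (k in seq_along(c("H2", "H5", "LE1", "LE2"))) {
      nm <- c("H2", "H5", "LE1", "LE2")[k]
      expect_equal(substr(seqs, co[[nm]] + 1, co[[nm]] + 1), arr[k])
    }
    fro <- strsplit(sigs$froger[i], "")[[1]]
    for (k in 1:5) {
      nm <- paste0("P", k)
      expect_equal(substr(seqs, co[[nm]] + 1, co[[nm]] + 1), fro[k])
    }
  }
})

test_that("signature grouping partitions by exact component strings", {
  sigs <- tibble::tibble(
    id = sprintf("p%02d", 1:34),
    arR = rep("FHTR", 34),
    froger = c(rep("MSAFW", 20), rep("QSAFW", 14)),
    flags = replicate(34, character(0), simplify = FALSE)
  )
  g_arr <- group_by_signature(sigs, "arR")
  expect_equal(nrow(g_arr), 1L)
  expect_equal(g_arr$n, 34L)
  g_fp <- group_by_signature(sigs, "froger")
  expect_equal(nrow(g_fp), 2L)
  expect_equal(g_fp$value, c("MSAFW", "QSAFW"))
  expect_equal(g_fp$n, c(20L, 14L))

  empty <- group_by_signature(sigs[0, ], "arR")
  expect_equal(nrow(empty), 0L)

  flagged <- sigs
  flagged$flags[[1]] <- "position_unresolved:H2"
  g2 <- group_by_signature(flagged, "arR")
  expect_true("unresolved" %in% g2$value)
})
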