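test_that("template building is deterministic and internally consistent", {
  a <- build_template("PIP", 1)
  b <- build_template("PIP", 1)
  expect_identical(a$sequence, b$sequence)
  expect_error(build_template("PIP", 9), class = "aqpkit_input_error")

  refs <- aqp_reference_set()
  expect_equal(nrow(refs), 19L)
  for (r in seq_len(nrow(refs))) {
    pos <- refs$positions[[r]]
    seqs <- refs$sequence[r]
    expect_equal(substr(seqs, pos[["NPA1_N"]] + 1, pos[["NPA1_N"]] + 1), "N")
    expect_equal(substr(seqs, pos[["NPA2_N"]] + 1, pos[["NPA2_N"]] + 1), "N")
    expect_gte(nchar(seqs), 250)
    expect_lte(nchar(seqs), 320)
  }
  # loop-B tripeptide variants: NPT in SIP1, NPV in XIPs
  lb3 <- function(id) {
    r <- refs[refs$id == id, ]
    substr(r$sequence, r$positions[[1]][["NPA1_N"]] + 1,
           r$positions[[1]][["NPA1_N"]] + 3)
  }
  expect_equal(lb3("ref_SIP1"), "NPT")
  expect_equal(lb3("ref_SIP2"), "NPL")
  expect_equal(lb3("ref_XIP1"), "NPV")
})

test_that("family simulation is byte-identical under a fixed seed", {
  spec <- tibble::tibble(subfamily = c("PIP", "NIP"), group = c(2L, 5L),
                         n = 3L)
  a <- simulate_family(spec, divergence = 0.2, seed = 5)
  b <- simulate_family(spec, divergence = 0.2, seed = 5)
  expect_identical(a$proteins, b$proteins)
  c <- simulate_family(spec, divergence = 0.2, seed = 6)
  expect_false(identical(a$proteins$sequence, c$proteins$sequence))
})

test_that("divergence zero reproduces the templates exactly", {
  spec <- tibble::tibble(subfamily = "TIP", group = 3L, n = 2L)
  fam <- simulate_family(spec, divergence = 0, seed = 1)
  tpl <- build_template("TIP", 3)
  expect_true(all(fam$proteins$sequence == tpl$sequence))
  expect_true(all(fam$manifest$n_mutations == 0))
})

test_that("mutations never touch protected signature positions", {
  spec <- tibble::tibble(subfamily = "NIP", group = 2L, n = 5L)
  fam <- simulate_family(spec, divergence = 0.4, seed = 9)
  tpl <- build_template("NIP", 2)
  pos <- tpl$positions[[1]]
  for (s in fam$proteins$sequence) {
    expect_equal(substr(s, pos[["NPA1_N"]] - 4, pos[["NPA1_N"]] + 5),
                 tpl$lb)
    expect_equal(substr(s, pos[["NPA2_N"]] - 3, pos[["NPA2_N"]] + 7),
                 tpl$le)
    for (nm in c("H2", "H5", "P1", "P2", "P3", "P4", "P5")) {
      expect_equal(substr(s, pos[[nm]] + 1, pos[[nm]] + 1),
                   substr(tpl$sequence, pos[[nm]] + 1, pos[[nm]] + 1))
    }
  }
})

test_that("planted signatures contain their intended substrate in raw mode", {
  refs <- aqp_reference_set()
  intended <- c(ref_PIP1 = "CO2", ref_TIP2 = "NH3", ref_NIP2 = "Si",
                ref_NIP5 = "Bo", ref_XIP1 = "U")
  for (id in names(intended)) {
    r <- refs[refs$id == id, ]
    sig <- tibble::tibble(id = id, arR = r$arR, froger = r$fp,
                          lb_region = r$lb, le_region = r$le,
                          coords = list(NULL), flags = list(character(0)),
                          subfamily = r$subfamily, group = r$group)
    det <- predict_substrates(sig, mode = "raw")
    expect_true(det$raw_match[det$substrate == intended[[id]]], info = id)
  }
})

test_that("FPKM simulation respects the planted decision boundary", {
  for (seed in c(1, 2)) {
    sim <- simulate_fpkm(n_genes = 50, seed = seed, expressed_fraction = 0.5)
    calls <- call_expression(sim$expression)
    joined <- dplyr::inner_join(calls, sim$manifest,
                                by = c("gene_id", "condition"))
    expect_equal(joined$expressed.x, joined$expressed.y)
  }
  all_on <- simulate_fpkm(n_genes = 20, seed = 3, expressed_fraction = 1)
  expect_true(all(call_expression(all_on$expression)$expressed))
  all_off <- simulate_fpkm(n_genes = 20, seed = 3, expressed_fraction = 0)
  expect_false(any(call_expression(all_off$expression)$expressed))
})

test_that("gene model simulation is deterministic and respects counts", {
  a <- simulate_gene_models(c(x = 2L, y = 0L), seed = 4)
  b <- simulate_gene_models(c(x = 2L, y = 0L), seed = 4)
  expect_identical(a$models, b$models)
  expect_equal(sum(a$models$transcript_id == "y.t1"), 1L)
  expect_error(simulate_gene_models(c(x = -1L)),
               class = "aqpkit_input_error")
})
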