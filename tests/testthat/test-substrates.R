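make_sig <- function(id, arR, lb, le, fp, subfamily = NA, group = NA) {
  tibble::tibble(id = id, arR = arR, froger = fp, lb_region = lb,
                 le_region = le, coords = list(NULL),
                 flags = list(character(0)),
                 subfamily = subfamily, group = group)
}

test_that("pattern compilation handles brackets, singletons and errors", {
  expect_equal(compile_pattern("[AGI][ISV][GA]R"),
               list(c("A", "G", "I"), c("I", "S", "V"), c("G", "A"), "R"))
  expect_equal(compile_pattern("GSGR"), list("G", "S", "G", "R"))
  expect_error(compile_pattern("[]A"), class = "aqpkit_syntax_error")
  expect_error(compile_pattern("[GA"), class = "aqpkit_syntax_error")
  expect_error(compile_pattern("G]A"), class = "aqpkit_syntax_error")
  expect_error(compile_pattern("gsgr"), class = "aqpkit_syntax_error")
})

test_that("component matching reports the first failing position", {
  expect_true(match_component("FHTR", compile_pattern("FHTR"))$match)
  expect_true(match_component("QSAFW", compile_pattern("[MQ]SAFW"))$match)
  m <- match_component("FHTR", compile_pattern("GSGR"))
  expect_false(m$match)
  expect_equal(m$first_fail, 1L)
  expect_error(match_component("FHT", compile_pattern("GSGR")),
               class = "aqpkit_input_error")
})

test_that("the matcher agrees with a Cartesian-product oracle on every row", {
  sdp <- load_sdp_table()
  set.seed(29)
  for (i in seq_len(nrow(sdp))) {
    for (col in c("arR_classes", "lb_classes", "le_classes", "fp_classes")) {
      classes <- sdp[[col]][[i]]
      members <- oracle_pattern_strings(classes)
      expect_lte(length(members), 1e5)
      # every enumerated member matches
      for (s in sample(members, min(25, length(members)))) {
        expect_true(match_component(s, classes)$match)
      }
      # mutated members fail exactly when the residue leaves its class
      for (k in 1:10) {
        s <- sample(members, 1)
        pos <- sample(length(classes), 1)
        repl <- sample(setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G",
                                 "H", "I", "L", "K", "M", "F", "P", "S",
                                 "T", "W", "Y", "V"), ""), 1)
        mutated <- s
        substr(mutated, pos, pos) <- repl
        expect_equal(match_component(mutated, classes)$match,
                     mutated %in% members)
      }
    }
  }
})

test_that("canonical signatures raw-match their substrates", {
  pip <- make_sig("pip", "FHTR", "SGGHINPAVT", "GTGINPARSLG", "MSAFW",
                  subfamily = "PIP", group = 1L)
  det <- predict_substrates(pip)
  expect_true(det$raw_match[det$substrate == "CO2"])
  expect_true(det$restricted_match[det$substrate == "CO2"])

  nip2 <- make_sig("nip2", "GSGR", "SGAHMNPAVT", "GGSMNPARTLG", "LTAYF",
                   subfamily = "NIP", group = 2L)
  det2 <- predict_substrates(nip2)
  raw <- det2$substrate[det2$raw_match]
  expect_true(all(c("Si", "As", "Sb", "U") %in% raw))
  expect_true(det2$restricted_match[det2$substrate == "Si"])
  expect_false(det2$restricted_match[det2$substrate == "U"])

  # a PIP filter can never satisfy the Si row
  expect_false(det$raw_match[det$substrate == "Si"])
  expect_equal(det$first_fail[det$substrate == "Si"], "arR")
})

test_that("restricted calls are a subset of raw calls and gates apply", {
  w <- classified_world(0.15, n_per_subfamily = 5L, seed = 8L,
                        with_signatures = TRUE)
  det <- predict_substrates(w$sigs)
  expect_true(all(!det$restricted_match | det$raw_match))
  # CO2 is gated to PIPs
  co2 <- det[det$substrate == "CO2" & det$restricted_match, ]
  called_sub <- w$cls$subfamily[match(co2$id, w$cls$id)]
  expect_true(all(called_sub == "PIP"))
})

test_that("flagged signatures match nothing", {
  sig <- make_sig("bad", "FHTR", "SGGHINPAVT", "GTGINPARSLG", "MSAFW")
  sig$flags <- list("position_unresolved:H2")
  det <- predict_substrates(sig)
  expect_false(any(det$raw_match))
})

test_that("enlarging a residue class never removes a raw match", {
  sdp <- load_sdp_table()
  i <- which(sdp$substrate == "Si")
  sig <- make_sig("nip2", "GSGR", "SGAHMNPAVT", "GGSMNPARTLG", "LTAYF")
  stopifnot(match_component(sig$arR, sdp$arR_classes[[i]])$match)
  for (pos in 1:4) {
    widened <- sdp$arR_classes[[i]]
    widened[[pos]] <- union(widened[[pos]], c("W", "K"))
    expect_true(match_component(sig$arR, widened)$match)
  }
})

test_that("printed rosters expand per the range notation", {
  expect_equal(expand_roster("NtPIP1;4–8"),
               paste0("NtPIP1;", 4:8))
  expect_equal(expand_roster("NtPIP1;4-8"), paste0("NtPIP1;", 4:8))
  expect_equal(expand_roster("NtNIP2;1"), "NtNIP2;1")
  expect_error(expand_roster("NtPIP1;8–4"), class = "aqpkit_range_error")
  sdp <- load_sdp_table()
  co2 <- expand_roster(sdp$roster[sdp$substrate == "CO2"][[1]])
  expect_length(co2, 12L)
})

test_that("roster summaries count names by subfamily", {
  rs <- roster_summary()
  expect_equal(rs$n_total[rs$substrate == "As"], 10L)
  expect_equal(rs$NIP[rs$substrate == "As"], 10L)
  expect_equal(rs$n_total[rs$substrate == "Sb"], 0L)
  expect_equal(rs$n_total[rs$substrate == "Si"], 1L)
})
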