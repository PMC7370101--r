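# Shared synthetic worlds, generated once per test run and memoised, since
# classification against the 19-reference panel is the slow step.

.world_cache <- new.env(parent = emptyenv())

# n records per subfamily, spread across that subfamily's groups.
family_spec_per_subfamily <- function(n_per_subfamily = 50L) {
  refs <- aqp_reference_set()
  groups <- dplyr::distinct(refs[, c("subfamily", "group")])
  out <- dplyr::group_by(groups, subfamily) |>
    dplyr::group_modify(function(df, key) {
      k <- nrow(df)
      base <- n_per_subfamily %/% k
      extra <- n_per_subfamily %% k
      df$n <- base + as.integer(seq_len(k) <= extra)
      df
    }) |>
    dplyr::ungroup()
  out[, c("subfamily", "group", "n")]
}

# A classified (and, for the default divergence, signature-extracted) world.
classified_world <- function(divergence, n_per_subfamily = 50L, seed = 42L,
                             with_signatures = FALSE) {
  key <- sprintf("d%s_n%d_s%d", divergence, n_per_subfamily, seed)
  if (is.null(.world_cache[[key]])) {
    fam <- simulate_family(family_spec_per_subfamily(n_per_subfamily),
                           divergence = divergence, seed = seed)
    cls <- classify_proteins(fam$proteins)
    .world_cache[[key]] <- list(fam = fam, cls = cls, sigs = NULL)
  }
  w <- .world_cache[[key]]
  if (with_signatures && is.null(w$sigs)) {
    w$sigs <- extract_signatures(w$fam$proteins, classification = w$cls)
    .world_cache[[key]] <- w
  }
  w
}
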