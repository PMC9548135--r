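# Fixture builders shared across the suite.

# Hand-built read-count profile with library metadata, bypassing simulation.
make_profile <- function(taxa, labels, reads, library_id = "lib1", kit = "Tn5_V",
                         input_pg = 5, replicate = 1L) {
  structure(
    data.frame(taxon = taxa, label = labels, reads = as.integer(reads),
               stringsAsFactors = FALSE),
    library_id = library_id, kit = kit, input_pg = input_pg,
    replicate = replicate, total_depth = sum(reads),
    class = c("read_count_profile", "data.frame")
  )
}

# Random abundance profile over a shared alphabet (for metric properties).
random_abundance <- function(n_taxa = 6, alphabet = letters[1:10]) {
  taxa <- sample(alphabet, n_taxa)
  x <- stats::rexp(n_taxa)
  stats::setNames(x / sum(x), taxa)
}

# A small dilution-series fixture for one kit: counts chosen so that taxon
# behaviour under the frequency/prevalence tests is known by construction.
toy_kit_profiles <- function(kit = "Tn5_V", inputs = c(50, 5, 0.5), depth = 1000) {
  profs <- list()
  for (i in seq_along(inputs)) {
    id <- sprintf("%s_%gpg", kit, inputs[i])
    cont <- round(depth * 0.02 * 50 / inputs[i] / (1 + 0.02 * 50 / inputs[i]))
    profs[[id]] <- make_profile(
      c("seq_1", "seq_2", "Ralstonia"),
      c("sequins", "sequins", "kit_contaminant"),
      c(depth - cont - round(depth * 0.3), round(depth * 0.3), cont),
      library_id = id, kit = kit, input_pg = inputs[i]
    )
  }
  for (j in 1:2) {
    id <- sprintf("%s_NC%d", kit, j)
    profs[[id]] <- make_profile(
      c("seq_1", "seq_2", "Ralstonia"),
      c("sequins", "sequins", "kit_contaminant"),
      c(0, 0, depth),
      library_id = id, kit = kit, input_pg = 0
    )
  }
  profs
}

# Independent Jensen-Shannon oracle: direct KL-to-mixture computation.
jsd_oracle <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i], base = 2)
    s
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}
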