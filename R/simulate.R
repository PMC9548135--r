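# Count-level simulation of libraries and whole dilution-series experiments.

new_profile <- function(tab, meta) {
  stopifnot(all(c("taxon", "label", "reads") %in% names(tab)))
  structure(
    tab,
    library_id = meta$library_id, kit = meta$kit, input_pg = meta$input_pg,
    replicate = meta$replicate, wga = meta$wga %||% FALSE,
    total_depth = sum(tab$reads),
    n_molecules = meta$n_molecules, n_unique_molecules = meta$n_unique_molecules,
    class = c("read_count_profile", "data.frame")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.read_count_profile <- function(x, ...) {
  cat(sprintf(
    "Read-count profile '%s' (kit %s, input %g pg, rep %s): %d taxa, %d reads\n",
    attr(x, "library_id"), attr(x, "kit"), attr(x, "input_pg"),
    attr(x, "replicate"), nrow(x), attr(x, "total_depth")
  ))
  by_label <- tapply(x$reads, x$label, sum)
  for (l in names(by_label)) cat(sprintf("  %-24s %d reads\n", l, by_label[[l]]))
  invisible(x)
}

# Unique molecules hit when `n_reads` reads are drawn with replacement from
# `n_molecules` library molecules; basis of the duplication-rate model.
#' Simulate duplicate structure of a finite-complexity library
#'
#' Draws `n_reads` reads with replacement from `n_molecules` unique library
#' molecules and returns the number of distinct molecules observed. The
#' expectation is `M * (1 - (1 - 1/M)^D)`.
#'
#' @param n_molecules Number of unique molecules in the library.
#' @param n_reads Number of sequenced reads.
#' @return Integer count of unique molecules observed.
#' @export
simulate_duplication <- function(n_molecules, n_reads) {
  stopifnot(n_molecules >= 1, n_reads >= 0)
  if (n_reads == 0) return(0L)
  length(unique(sample.int(n_molecules, n_reads, replace = TRUE)))
}

#' Simulate one library as a truth-labelled count profile
#'
#' Generates the classified read counts of a single library. The expected
#' share of sequins reads before bias is `input / (input + contaminant mass)`,
#' where the kit contaminant mass is drawn lognormally around the pool's
#' median load and endogenous contaminant mass is a fixed fraction of the
#' input. Within sequins, expected shares are proportional to
#' `mass_fraction * exp(bias)` with GC/length (and WGA) bias terms. Counts are
#' drawn once from a single multinomial at `config$depth`. Negative controls
#' (input 0) contain no sequins and no endogenous reads. Library complexity is
#' tracked by resampling reads from a finite molecule pool sized from the
#' total DNA mass and a kit-specific recovery factor, which yields the
#' duplication-rate bookkeeping used by [duplication_rate()].
#'
#' @param design A `community_design`.
#' @param config A `library_config`; `config$kit` must match `pool$kit`.
#' @param pool A `contaminant_pool`.
#' @param bias A `bias_model`.
#' @param endogenous Data frame of endogenous genera (`genus`, `fraction` of
#'   input mass); see [default_endogenous()].
#' @param recovery Kit recovery factor for the molecule-pool size; defaults to
#'   a per-kit constant.
#' @return A `read_count_profile`: data frame with columns `taxon`, `label`
#'   (one of `sequins`, `kit_contaminant`, `endogenous_contaminant`) and
#'   `reads`, with library metadata in attributes.
#' @export
simulate_library <- function(design, config, pool, bias = bias_model(),
                             endogenous = default_endogenous(),
                             recovery = NULL) {
  stopifnot(inherits(design, "community_design"), inherits(config, "library_config"),
            inherits(pool, "contaminant_pool"), inherits(bias, "bias_model"))
  if (!identical(pool$kit, config$kit)) stop("pool kit does not match config kit")
  if (config$depth <= 0) stop("invalid config: depth must be positive")
  if (is.null(recovery)) {
    recovery <- if (config$kit %in% names(KIT_RECOVERY)) KIT_RECOVERY[[config$kit]] else 0.05
  }
  comp <- design$components
  genera <- pool$genera
  taxa <- c(comp$id, genera$genus, endogenous$genus)
  if (anyDuplicated(taxa)) stop("taxon id collision between sequins, pool and endogenous genera")

  with_seed(config$seed, {
    load_pg <- rlnorm(1, log(pool$load_median_pg), pool$load_dispersion)
    w <- rlnorm(nrow(genera), genera$meanlog, genera$sdlog)
    kit_mass <- load_pg * w / sum(w)

    input <- config$input_mass_pg
    endo_mass <- endogenous$fraction * input

    z <- bias$gc_coefficient * (comp$gc - 0.5) +
      bias$length_coefficient * (comp$length_bp / 1000)
    if (config$wga) {
      z <- z + bias$wga_gc_coefficient * (comp$gc - 0.5) +
        bias$wga_length_coefficient * (comp$length_bp / 1000)
    }
    seq_w <- comp$mass_fraction * exp(z)
    seq_mass <- if (input > 0) input * seq_w / sum(seq_w) else numeric(nrow(comp))

    mass <- c(seq_mass, kit_mass, endo_mass)
    if (sum(mass) <= 0) stop("library has no DNA mass (zero input and zero contaminant load)")
    counts <- as.vector(rmultinom(1, config$depth, mass / sum(mass)))

    # finite-complexity bookkeeping: contaminant fragments get a nominal 5 kb
    mean_len <- sum(c(seq_mass * comp$length_bp, (kit_mass) * 5000, endo_mass * 5000)) / sum(mass)
    n_mol <- max(1, round(sum(mass) * .molecules_per_pg(mean_len) * recovery))
    n_unique <- simulate_duplication(n_mol, config$depth)

    tab <- data.frame(
      taxon = taxa,
      label = c(
        rep("sequins", nrow(comp)),
        rep("kit_contaminant", nrow(genera)),
        rep("endogenous_contaminant", nrow(endogenous))
      ),
      reads = counts,
      stringsAsFactors = FALSE
    )
    out <- new_profile(tab, list(
      library_id = config$library_id, kit = config$kit, input_pg = input,
      replicate = config$replicate, wga = config$wga,
      n_molecules = n_mol, n_unique_molecules = n_unique
    ))
    # ground-truth masses, for parameter-recovery checks
    attr(out, "contaminant_load_pg") <- load_pg
    attr(out, "endogenous_mass_pg") <- sum(endo_mass)
    out
  })
}

#' Simulate a full dilution-series experiment
#'
#' Produces one library per (kit, input, replicate) combination plus `n_nc`
#' negative controls per kit. Per-library seeds are derived deterministically
#' from the master seed and the library id, so the same master seed always
#' yields identical profiles.
#'
#' @param design A `community_design`.
#' @param kits Character vector of kits to simulate.
#' @param dilutions_pg Input dilution series in pg (default
#'   `c(5000, 500, 50, 5, 0.5)`).
#' @param replicates Number of replicates per (kit, input).
#' @param pools Named list of `contaminant_pool`s covering every kit.
#' @param bias A `bias_model`.
#' @param endogenous Endogenous-genus table; see [default_endogenous()].
#' @param n_nc Negative controls per kit (minimum 2).
#' @param depth Sequencing depth per library.
#' @param wga Whether libraries are WGA-amplified.
#' @param seed Master seed.
#' @return Named list of `read_count_profile`s.
#' @examples
#' d <- mock_design(seed = 1)
#' profs <- simulate_experiment(d, kits = "Tn5_V", dilutions_pg = c(50, 5),
#'                              depth = 1e4, seed = 1)
#' length(profs) # 2 inputs x 2 reps + 2 NCs
#' @export
simulate_experiment <- function(design, kits = KITS,
                                dilutions_pg = c(5000, 500, 50, 5, 0.5),
                                replicates = 2, pools = default_pools(kits),
                                bias = bias_model(),
                                endogenous = default_endogenous(),
                                n_nc = 2, depth = 1e6, wga = FALSE, seed = 1) {
  if (length(kits) < 1) stop("invalid config: need at least one kit")
  if (length(dilutions_pg) < 1) stop("invalid config: need at least one input level")
  if (n_nc < 2) stop("invalid config: need at least 2 negative controls per kit")
  missing_pools <- setdiff(kits, names(pools))
  if (length(missing_pools)) {
    stop("invalid config: no contaminant pool for kit(s) ", paste(missing_pools, collapse = ", "))
  }
  profiles <- list()
  for (k in kits) {
    for (inp in dilutions_pg) {
      for (r in seq_len(replicates)) {
        id <- sprintf("%s_%gpg_r%d", k, inp, r)
        cfg <- library_config(id, k, inp, replicate = r, wga = wga,
                              depth = depth, seed = derive_seed(seed, id))
        profiles[[id]] <- simulate_library(design, cfg, pools[[k]], bias, endogenous)
      }
    }
    for (j in seq_len(n_nc)) {
      id <- sprintf("%s_NC%d", k, j)
      cfg <- library_config(id, k, 0, replicate = j, wga = wga,
                            depth = depth, seed = derive_seed(seed, id))
      profiles[[id]] <- simulate_library(design, cfg, pools[[k]], bias, endogenous)
    }
  }
  profiles
}

# Metadata helpers used across modules.
profile_meta <- function(profile, field) attr(profile, field)

#' Drop taxa from a profile
#'
#' Removes the given taxa (e.g. flagged endogenous contaminants) from a
#' count profile, preserving library metadata and updating the total depth.
#'
#' @param profile A `read_count_profile`.
#' @param taxa Character vector of taxon ids to remove.
#' @return The filtered `read_count_profile`.
#' @export
drop_taxa <- function(profile, taxa) {
  out <- profile[!profile$taxon %in% taxa, , drop = FALSE]
  for (a in c("library_id", "kit", "input_pg", "replicate", "wga",
              "n_molecules", "n_unique_molecules")) {
    attr(out, a) <- attr(profile, a)
  }
  attr(out, "total_depth") <- sum(out$reads)
  class(out) <- class(profile)
  out
}

#' Flatten a list of profiles into one table
#'
#' @param profiles List of `read_count_profile`s.
#' @param drop_zero Drop rows with zero reads (default FALSE).
#' @return Data frame with columns `library_id`, `kit`, `input_pg`,
#'   `replicate`, `taxon`, `label`, `reads`.
#' @export
profiles_to_table <- function(profiles, drop_zero = FALSE) {
  rows <- lapply(profiles, function(p) {
    tab <- as.data.frame(p)
    if (drop_zero) tab <- tab[tab$reads > 0, , drop = FALSE]
    data.frame(
      library_id = attr(p, "library_id"), kit = attr(p, "kit"),
      input_pg = attr(p, "input_pg"), replicate = attr(p, "replicate"),
      taxon = tab$taxon, label = tab$label, reads = tab$reads,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
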