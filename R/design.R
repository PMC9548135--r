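# Ground-truth mock-community designs, contaminant pools and bias models.

#' Build a staggered mock-community design
#'
#' Constructs the ground truth for a sequins-like synthetic community:
#' `n_components` artificial sequences assigned to `n_tiers` concentration
#' tiers combined at twofold serial dilutions, so the molar range spans
#' `2^(n_tiers - 1)`-fold (128-fold for the default 8 tiers). Every tier
#' receives at least five components. GC content is drawn uniformly on
#' [0.294, 0.7106] and lengths on [1929, 9120] bp, the ranges covered by the
#' synthetic standards. Because shotgun reads sample bases rather than
#' molecules, the expected read share of a component is its *mass* fraction:
#' `mass_fraction` is proportional to `molar_level * length_bp`, renormalised.
#'
#' @param n_components Number of components (default 83).
#' @param n_tiers Number of twofold concentration tiers (default 8).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return An object of class `community_design`: a list with `components`
#'   (data frame with columns `id`, `length_bp`, `gc`, `tier`, `molar_level`,
#'   `mass_fraction`) and `n_tiers`.
#' @examples
#' d <- mock_design(seed = 1)
#' table(d$components$tier)
#' @export
mock_design <- function(n_components = 83, n_tiers = 8, seed = 1) {
  if (n_tiers < 2) stop("n_tiers must be at least 2")
  if (n_components < 5 * n_tiers) {
    stop("invalid design: need at least 5 components per tier (n_components >= 5 * n_tiers)")
  }
  comp <- with_seed(derive_seed(seed, "mock_design"), {
    base <- rep(seq_len(n_tiers), each = 5L)
    extra <- sample.int(n_tiers, n_components - 5L * n_tiers, replace = TRUE)
    tier <- sample(c(base, extra))
    data.frame(
      id = sprintf("sequin_%03d", seq_len(n_components)),
      length_bp = sample(1929:9120, n_components, replace = TRUE),
      gc = runif(n_components, 0.294, 0.7106),
      tier = tier,
      stringsAsFactors = FALSE
    )
  })
  # tier 1 is the most concentrated; twofold ladder down to tier n_tiers
  comp$molar_level <- 2^(n_tiers - comp$tier)
  mass <- comp$molar_level * comp$length_bp
  comp$mass_fraction <- mass / sum(mass)
  design <- structure(
    list(components = comp, n_tiers = as.integer(n_tiers)),
    class = "community_design"
  )
  validate_design(design)
  design
}

#' Validate a community design
#'
#' Checks the structural invariants of a [mock_design()] object: mass
#' fractions positive and summing to one, every tier populated with at least
#' five components, GC and length within the supported ranges, and an exact
#' `2^(n_tiers - 1)` molar ratio between the extreme tiers.
#'
#' @param design A `community_design`.
#' @return The design, invisibly; stops on violation.
#' @export
validate_design <- function(design) {
  comp <- design$components
  if (any(comp$mass_fraction <= 0)) stop("invalid design: non-positive mass fraction")
  if (abs(sum(comp$mass_fraction) - 1) > 1e-9) stop("invalid design: mass fractions must sum to 1")
  tiers <- sort(unique(comp$tier))
  if (!identical(tiers, seq_len(design$n_tiers))) {
    stop("invalid design: tiers must be exactly 1..n_tiers")
  }
  if (any(table(comp$tier) < 5)) stop("invalid design: every tier needs >= 5 components")
  if (any(comp$length_bp < 1929 | comp$length_bp > 9120)) {
    stop("invalid design: component length outside [1929, 9120] bp")
  }
  if (any(comp$gc < 0.294 | comp$gc > 0.7106)) {
    stop("invalid design: component GC outside [0.294, 0.7106]")
  }
  ratio <- max(comp$molar_level) / min(comp$molar_level)
  if (abs(ratio - 2^(design$n_tiers - 1)) > 1e-9) {
    stop("invalid design: molar range must equal 2^(n_tiers - 1)")
  }
  if (anyDuplicated(comp$id)) stop("invalid design: duplicated component ids")
  invisible(design)
}

#' @export
print.community_design <- function(x, ...) {
  cat(sprintf(
    "Mock community design: %d components, %d tiers (%.0f-fold molar range)\n",
    nrow(x$components), x$n_tiers, 2^(x$n_tiers - 1)
  ))
  cat(sprintf(
    "  length %d-%d bp, GC %.1f-%.1f%%\n",
    min(x$components$length_bp), max(x$components$length_bp),
    100 * min(x$components$gc), 100 * max(x$components$gc)
  ))
  invisible(x)
}

# Genus names commonly reported as reagent ("kitome") contaminants; used to
# seed the shared core of the default contaminant pools.
.KITOME_GENERA <- c(
  "Ralstonia", "Burkholderia", "Bradyrhizobium", "Pseudomonas", "Sphingomonas",
  "Cutibacterium", "Acinetobacter", "Methylobacterium", "Mesorhizobium",
  "Stenotrophomonas", "Delftia", "Herbaspirillum", "Comamonas", "Aquabacterium",
  "Phyllobacterium", "Variovorax", "Afipia", "Ochrobactrum", "Rhodococcus",
  "Streptococcus", "Staphylococcus", "Corynebacterium", "Micrococcus",
  "Bacillus", "Paenibacillus", "Deinococcus", "Curtobacterium",
  "Janthinobacterium", "Massilia", "Duganella", "Pelomonas", "Undibacterium",
  "Novosphingobium", "Sphingobium", "Sphingopyxis", "Brevundimonas",
  "Caulobacter", "Microbacterium", "Kocuria", "Dietzia"
)

#' Construct a kit-specific contaminant pool
#'
#' A contaminant pool describes the background DNA a library-preparation kit
#' introduces: a set of genera with lognormal relative-mass parameters, the
#' median total contaminant load in pg, and the across-library dispersion of
#' that load.
#'
#' @param kit Kit name, one of `r paste(KITS, collapse = ", ")`.
#' @param genera Data frame with columns `genus`, `shared` (logical: part of
#'   the core shared by all kits), `meanlog`, `sdlog` (lognormal relative-mass
#'   parameters per library draw).
#' @param load_median_pg Median contaminant load (pg).
#' @param load_dispersion Lognormal sdlog of the per-library load draw.
#' @return An object of class `contaminant_pool`.
#' @export
contaminant_pool <- function(kit, genera, load_median_pg, load_dispersion = KIT_LOAD_SDLOG) {
  stopifnot(
    is.character(kit), length(kit) == 1L,
    is.data.frame(genera),
    all(c("genus", "shared", "meanlog", "sdlog") %in% names(genera))
  )
  if (!is.numeric(load_median_pg) || load_median_pg < 0) {
    stop("load_median_pg must be non-negative (0 disables kit contamination)")
  }
  if (load_dispersion <= 0) stop("load_dispersion must be positive")
  if (anyDuplicated(genera$genus)) stop("duplicated genus in contaminant pool")
  structure(
    list(
      kit = kit, genera = genera,
      load_median_pg = load_median_pg, load_dispersion = load_dispersion
    ),
    class = "contaminant_pool"
  )
}

#' Default contaminant pools for the five modelled kits
#'
#' Builds one pool per kit with `n_shared` core genera common to every kit
#' (the shared "kitome") plus `n_unique` genera private to each kit. Shared
#' genera carry a fixed abundance ladder (`meanlog` spread over \[0, -4\]) so
#' pools are uneven, mimicking the skewed composition of reagent
#' contamination; the per-library draw dispersion (`sdlog`) is kit specific.
#' Load medians default to `r paste(sprintf("%s %.2f", names(KIT_LOAD_MEDIAN_PG), KIT_LOAD_MEDIAN_PG), collapse = ", ")` pg.
#'
#' @param kits Character vector of kit names.
#' @param n_shared Number of shared core genera (default 63).
#' @param n_unique Number of kit-private genera per kit (default 20).
#' @param load_median_pg Named numeric of load medians per kit.
#' @param load_dispersion Lognormal sdlog of the load draw.
#' @param genus_sdlog Named numeric of per-kit genus-abundance dispersion.
#' @return Named list of `contaminant_pool` objects.
#' @export
default_pools <- function(kits = KITS, n_shared = 63, n_unique = 20,
                          load_median_pg = KIT_LOAD_MEDIAN_PG,
                          load_dispersion = KIT_LOAD_SDLOG,
                          genus_sdlog = KIT_GENUS_SDLOG) {
  shared_names <- c(
    .KITOME_GENERA[seq_len(min(n_shared, length(.KITOME_GENERA)))],
    if (n_shared > length(.KITOME_GENERA)) {
      sprintf("Kitome_genus_%02d", seq_len(n_shared - length(.KITOME_GENERA)))
    }
  )
  shared_meanlog <- seq(0, -4, length.out = n_shared)
  pools <- lapply(kits, function(k) {
    genera <- data.frame(
      genus = c(shared_names, if (n_unique > 0) sprintf("%s_genus_%02d", k, seq_len(n_unique))),
      shared = c(rep(TRUE, n_shared), rep(FALSE, n_unique)),
      meanlog = c(shared_meanlog, rep(-2, n_unique)),
      sdlog = unname(genus_sdlog[[k]]),
      stringsAsFactors = FALSE
    )
    contaminant_pool(k, genera, unname(load_median_pg[[k]]), load_dispersion)
  })
  names(pools) <- kits
  pools
}

#' Default endogenous contaminants
#'
#' Endogenous contaminants reside in the template material itself, so their
#' mass scales with the input amount rather than with the kit. The default
#' models five genera jointly carrying 1% of the input mass.
#'
#' @return Data frame with columns `genus` and `fraction` (of input mass).
#' @export
default_endogenous <- function() {
  data.frame(
    genus = c("Escherichia", "Gammaretrovirus", "Citrobacter", "Mastadenovirus", "Shigella"),
    fraction = c(0.004, 0.0025, 0.0015, 0.001, 0.001),
    stringsAsFactors = FALSE
  )
}

#' Amplification bias model
#'
#' Multiplicative bias on the expected within-sequins read share of each
#' component: `exp(gc_coefficient * (gc - 0.5) + length_coefficient * kb)`,
#' with additional WGA terms applied when a library is whole-genome amplified
#' (WGA enriches longer fragments and depletes high-GC fragments, so its
#' length coefficient is positive and its GC coefficient negative). All-zero
#' coefficients give unbiased sampling.
#'
#' @param gc_coefficient Log-scale weight per unit GC deviation from 0.5.
#' @param length_coefficient Log-scale weight per kb of fragment length.
#' @param wga_gc_coefficient Additional GC weight for WGA libraries.
#' @param wga_length_coefficient Additional length weight for WGA libraries.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(gc_coefficient = -0.3, length_coefficient = 0.05,
                       wga_gc_coefficient = -2, wga_length_coefficient = 0.5) {
  coefs <- c(gc_coefficient, length_coefficient, wga_gc_coefficient, wga_length_coefficient)
  if (any(!is.finite(coefs))) stop("bias coefficients must be finite")
  structure(
    list(
      gc_coefficient = gc_coefficient,
      length_coefficient = length_coefficient,
      wga_gc_coefficient = wga_gc_coefficient,
      wga_length_coefficient = wga_length_coefficient
    ),
    class = "bias_model"
  )
}

#' Configuration of one simulated library
#'
#' @param library_id Unique library identifier.
#' @param kit Kit name.
#' @param input_mass_pg Template DNA input in pg; 0 denotes a negative control.
#' @param replicate Replicate index.
#' @param wga Whether the library is whole-genome amplified before prep.
#' @param n_pcr_cycles PCR cycles used in library amplification.
#' @param depth Sequencing depth (reads).
#' @param seed Integer seed for this library's RNG stream.
#' @return An object of class `library_config`.
#' @export
library_config <- function(library_id, kit, input_mass_pg, replicate = 1L,
                           wga = FALSE, n_pcr_cycles = 12L, depth = 1e6, seed = 1L) {
  if (!is.numeric(depth) || depth < 1) stop("invalid config: depth must be a positive integer")
  if (!is.numeric(input_mass_pg) || input_mass_pg < 0) {
    stop("invalid config: input_mass_pg must be non-negative")
  }
  if (n_pcr_cycles < 1) stop("invalid config: n_pcr_cycles must be positive")
  structure(
    list(
      library_id = library_id, kit = kit, input_mass_pg = input_mass_pg,
      replicate = as.integer(replicate), wga = isTRUE(wga),
      n_pcr_cycles = as.integer(n_pcr_cycles), depth = as.integer(depth),
      seed = as.integer(seed)
    ),
    class = "library_config"
  )
}
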