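# Absolute quantification and characterisation of contaminants.

contaminant_labels <- c("kit_contaminant", "endogenous_contaminant")

#' Quantify contaminating DNA against the spike-in scale
#'
#' Because the sequins input mass is known, the contaminant read:sequins read
#' ratio converts directly to mass: `mass = input_pg * contaminant_reads /
#' sequins_reads`. This assumes reads are proportional to mass identically
#' for sequins and contaminants (no length/GC correction), consistent with
#' the simulator's sampling model.
#'
#' @param profile A `read_count_profile`.
#' @param input_pg Sequins input mass in pg; defaults to the profile's
#'   `input_pg` attribute.
#' @param labels Which provenance labels count as contaminant reads.
#' @return List with `library_id` and `mass_pg`.
#' @examples
#' p <- structure(data.frame(taxon = c("s", "c"),
#'                           label = c("sequins", "kit_contaminant"),
#'                           reads = c(900, 100)),
#'                class = c("read_count_profile", "data.frame"))
#' contaminant_mass(p, input_pg = 0.5)$mass_pg  # 0.5 * 100/900
#' @export
contaminant_mass <- function(profile, input_pg = attr(profile, "input_pg"),
                             labels = contaminant_labels) {
  if (is.null(input_pg) || input_pg <= 0) stop("input_pg must be positive")
  seq_reads <- sum(profile$reads[profile$label == "sequins"])
  if (seq_reads == 0) stop("not quantifiable: profile contains no sequins reads")
  cont_reads <- sum(profile$reads[profile$label %in% labels])
  list(
    library_id = attr(profile, "library_id") %||% NA_character_,
    mass_pg = input_pg * cont_reads / seq_reads
  )
}

# contaminant-normalised abundance table: libraries x genera
contaminant_abundance_matrix <- function(profiles) {
  tabs <- lapply(profiles, function(p) {
    tab <- p[p$label %in% contaminant_labels, , drop = FALSE]
    total <- sum(tab$reads)
    stats::setNames(if (total > 0) tab$reads / total else rep(0, nrow(tab)), tab$taxon)
  })
  genera <- unique(unlist(lapply(tabs, names)))
  mat <- matrix(0, nrow = length(tabs), ncol = length(genera),
                dimnames = list(names(profiles), genera))
  for (i in seq_along(tabs)) mat[i, names(tabs[[i]])] <- tabs[[i]]
  mat
}

#' Screen for endogenous contaminants
#'
#' Endogenous contaminants originate from the template material, so their
#' abundance among contaminating reads rises with input mass while
#' reagent-borne contamination does not. For each kit, each genus's
#' contaminant-normalised abundance is regressed on `log10(input)` (the
#' dilution ladder is geometric) across positive libraries; p-values are
#' Benjamini-Hochberg corrected within kit. A genus is flagged when it shows
#' a positive slope with `p.adj < alpha` and `R^2 > r2_min` in at least
#' `min_kits` kits.
#'
#' @param profiles Named list of `read_count_profile`s spanning >= `min_kits`
#'   kits and >= 3 input levels per kit (negative controls are ignored).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param r2_min Minimum regression R-squared (default 0.55).
#' @param min_kits Minimum number of kits meeting the rule (default 4).
#' @param log_input Regress on `log10(input)` (default) or raw input.
#' @return Data frame with columns `genus`, `n_kits_significant`, `flagged`;
#'   per-kit statistics in `attr(, "per_kit")`.
#' @export
detect_endogenous <- function(profiles, alpha = 0.05, r2_min = 0.55,
                              min_kits = 4, log_input = TRUE) {
  kit <- vapply(profiles, attr, "", "kit")
  input <- vapply(profiles, attr, 0, "input_pg")
  pos <- input > 0
  per_kit <- list()
  for (k in unique(kit)) {
    sel <- pos & kit == k
    x_in <- input[sel]
    if (length(unique(x_in)) < 3) {
      stop("need at least 3 distinct input levels per kit (kit ", k, ")")
    }
    mat <- contaminant_abundance_matrix(profiles[sel])
    x <- if (log_input) log10(x_in) else x_in
    stats_k <- lapply(colnames(mat), function(g) {
      y <- mat[, g]
      if (stats::var(y) == 0) {
        return(data.frame(genus = g, slope = 0, r_squared = 0, p_value = 1))
      }
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      data.frame(
        genus = g, slope = unname(coef(fit)[2]),
        r_squared = sm$r.squared,
        p_value = unname(sm$coefficients[2, 4])
      )
    })
    tab <- do.call(rbind, stats_k)
    tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
    tab$kit <- k
    per_kit[[k]] <- tab
  }
  all_tab <- do.call(rbind, per_kit)
  rownames(all_tab) <- NULL
  hit <- all_tab$p_adjusted < alpha & all_tab$r_squared > r2_min & all_tab$slope > 0
  n_sig <- tapply(hit, all_tab$genus, sum)
  out <- data.frame(
    genus = names(n_sig),
    n_kits_significant = as.integer(n_sig),
    flagged = as.integer(n_sig) >= min_kits,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "per_kit") <- all_tab
  out
}

prevalent_genera <- function(profiles, abundance_min, prevalence_min) {
  mat <- contaminant_abundance_matrix(profiles)
  prev <- colMeans(mat > abundance_min)
  colnames(mat)[prev >= prevalence_min]
}

#' Core contaminant catalogue
#'
#' A genus is part of a kit's core contaminants when its
#' contaminant-normalised relative abundance exceeds `abundance_min` (default
#' 0.1%) in at least `prevalence_min` (default half) of that kit's libraries.
#' The shared core is the intersection over kits; each kit's unique core is
#' its core minus the union of every other kit's core.
#'
#' @param profiles Named list of `read_count_profile`s (>= 2 libraries per
#'   kit).
#' @param abundance_min Relative-abundance threshold (default 0.001).
#' @param prevalence_min Minimum fraction of libraries (default 0.5).
#' @return List with `core` (per-kit genus sets), `shared`, and `unique`
#'   (per-kit).
#' @export
core_contaminants <- function(profiles, abundance_min = 0.001, prevalence_min = 0.5) {
  kit <- vapply(profiles, attr, "", "kit")
  kits <- unique(kit)
  core <- lapply(kits, function(k) {
    sel <- profiles[kit == k]
    if (length(sel) < 2) stop("need at least 2 libraries per kit (kit ", k, ")")
    prevalent_genera(sel, abundance_min, prevalence_min)
  })
  names(core) <- kits
  if (all(lengths(core) == 0)) warning("no contaminant genus passed the core criteria")
  shared <- Reduce(intersect, core)
  uniq <- lapply(kits, function(k) setdiff(core[[k]], unlist(core[setdiff(kits, k)])))
  names(uniq) <- kits
  list(core = core, shared = shared, unique = uniq)
}

#' Dominant contaminants per kit
#'
#' Same rule as [core_contaminants()] but at a 1% abundance threshold: the
#' genera that dominate a kit's contamination.
#'
#' @inheritParams core_contaminants
#' @param abundance_min Relative-abundance threshold (default 0.01).
#' @return Named list of genus sets per kit.
#' @export
dominant_contaminants <- function(profiles, abundance_min = 0.01, prevalence_min = 0.5) {
  core_contaminants(profiles, abundance_min, prevalence_min)$core
}

#' Remaining-contaminant curve under abundance filtering
#'
#' For each threshold `t`, the fraction of contaminating reads carried by
#' taxa whose whole-library relative abundance is at least `t` -- i.e. the
#' contamination that survives filtering components below `t`. The curve is
#' non-increasing in `t` and reaches 0 beyond the most abundant contaminant.
#'
#' @param profile A `read_count_profile` with contaminant reads.
#' @param thresholds Numeric vector of relative-abundance thresholds.
#' @return Data frame with columns `threshold` and `remaining`.
#' @export
remaining_fraction_curve <- function(profile, thresholds) {
  total <- sum(profile$reads)
  cont <- profile[profile$label %in% contaminant_labels, , drop = FALSE]
  cont_total <- sum(cont$reads)
  if (cont_total == 0) stop("profile has no contaminant reads")
  rel <- cont$reads / total
  remaining <- vapply(
    thresholds,
    function(t) sum(cont$reads[rel >= t]) / cont_total,
    numeric(1)
  )
  data.frame(threshold = thresholds, remaining = remaining)
}
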