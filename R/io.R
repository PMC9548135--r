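# TSV/JSON/YAML artifacts: profiles, designs and run configurations.

#' Write profiles to a TSV file
#'
#' One row per (library, taxon) with fixed column order `library_id`, `kit`,
#' `input_pg`, `replicate`, `taxon`, `label`, `reads`.
#'
#' @param profiles List of `read_count_profile`s.
#' @param path Output path.
#' @param drop_zero Omit zero-count rows (default FALSE, so round trips are
#'   lossless).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, drop_zero = FALSE) {
  tab <- profiles_to_table(profiles, drop_zero = drop_zero)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read profiles from a TSV file
#'
#' Parses a table written by [write_profiles()] back into a named list of
#' `read_count_profile`s. Malformed rows abort with the offending line
#' number.
#'
#' @param path Input path.
#' @return Named list of `read_count_profile`s.
#' @export
read_profiles <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(
                      library_id = "character", kit = "character",
                      input_pg = "numeric", replicate = "integer",
                      taxon = "character", label = "character", reads = "integer"
                    ))
  required <- c("library_id", "kit", "input_pg", "replicate", "taxon", "label", "reads")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("profile table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(is.na(tab$reads) | tab$reads < 0 | is.na(tab$input_pg))
  if (length(bad)) stop("malformed profile row at line ", bad[1] + 1L)
  if (nrow(tab) == 0) return(list())
  split_tab <- split(tab, factor(tab$library_id, levels = unique(tab$library_id)))
  profiles <- lapply(split_tab, function(s) {
    if (anyDuplicated(s$taxon)) {
      stop("duplicated taxon in library ", s$library_id[1])
    }
    new_profile(
      data.frame(taxon = s$taxon, label = s$label, reads = s$reads,
                 stringsAsFactors = FALSE),
      list(library_id = s$library_id[1], kit = s$kit[1],
           input_pg = s$input_pg[1], replicate = s$replicate[1])
    )
  })
  profiles
}

#' Write / read a community design as JSON
#'
#' @param design A `community_design`.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` returns the
#'   design.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    list(n_tiers = design$n_tiers, components = design$components),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- structure(
    list(components = as.data.frame(obj$components), n_tiers = as.integer(obj$n_tiers)),
    class = "community_design"
  )
  validate_design(design)
  design
}

#' Default run configuration
#'
#' The configuration describing one full benchmarking run: the community
#' design parameters, kits, dilution series, replicate and negative-control
#' counts, sequencing depth, bias coefficients, decontamination methods and
#' threshold grid. All stochastic stages derive their streams from `seed`.
#'
#' @param seed Master seed (mandatory).
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param depth Sequencing depth per library.
#' @param kits Kits to simulate.
#' @param dilutions_pg Input dilution series (pg).
#' @param replicates Replicates per (kit, input).
#' @param n_nc Negative controls per kit.
#' @param methods Decontamination methods to evaluate; any of `fold5`,
#'   `fold10`, `frequency`, `prevalence`, `either`.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed, out_dir = NULL, depth = 1e6,
                               kits = KITS,
                               dilutions_pg = c(5000, 500, 50, 5, 0.5),
                               replicates = 2, n_nc = 2,
                               methods = c("fold5", "fold10", "frequency",
                                           "prevalence", "either")) {
  if (missing(seed)) stop("seed is mandatory")
  structure(
    list(
      seed = as.integer(seed),
      design = list(n_components = 83L, n_tiers = 8L),
      kits = kits,
      dilutions_pg = dilutions_pg,
      replicates = as.integer(replicates),
      n_nc = as.integer(n_nc),
      depth = depth,
      bias = unclass(bias_model()),
      grid = list(n = 40L, from = 0.1, to = 0.5),
      methods = methods,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration (JSON or YAML by extension)
#'
#' Serialisation round trips are lossless on all fields.
#'
#' @param config A `run_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the configuration.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(obj$seed)) stop("config lacks a seed")
  template <- default_run_config(seed = obj$seed)
  for (field in names(obj)) template[[field]] <- obj[[field]]
  template$seed <- as.integer(template$seed)
  template$replicates <- as.integer(template$replicates)
  template$n_nc <- as.integer(template$n_nc)
  template$design <- lapply(template$design, as.integer)
  template$grid$n <- as.integer(template$grid$n)
  template
}

# Cheap content hash for provenance stamping (rolling polynomial hash of the
# deparsed object).
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", derive_seed(0, txt))
}
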