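# Multi-group scenario generation: labelled sets of fields emulating an
# imaging experiment with per-group parameter contrasts (for example a
# fractional reduction of live-cell counts in a treated group).

#' Configure a multi-group imaging scenario
#'
#' @param groups Named list (>= 2 entries unless `allow_single_group`); each
#'   element is a (possibly empty) list of [inclusion_field_spec()] argument
#'   overrides applied on top of `base`.
#' @param n_fields Fields generated per group; default 12, a typical number
#'   of randomly captured images per experiment.
#' @param base Baseline [inclusion_field_spec()] shared by all groups.
#' @param seed Integer seed; per-field seeds are drawn from it.
#' @param allow_single_group Permit a single group (for plain batch
#'   generation).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(groups = list(
                              control = list(),
                              treated = list(n_live_nuclei = 10)),
                            n_fields = 12,
                            base = inclusion_field_spec(n_live_nuclei = 30),
                            seed = 1, allow_single_group = FALSE) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    abort("`groups` must be a named list.")
  if (length(groups) < 2 && !allow_single_group)
    abort("a scenario contrasts at least two groups.")
  check_scalar(n_fields, "n_fields", min = 1)
  spec_args <- names(formals(inclusion_field_spec))
  for (g in names(groups)) {
    bad <- setdiff(names(groups[[g]]), spec_args)
    if (length(bad))
      abort(sprintf("unknown field-spec override(s) in group '%s': %s",
                    g, paste(bad, collapse = ", ")))
  }
  structure(list(groups = groups, n_fields = as.integer(n_fields),
                 base = base, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate all fields of a scenario
#'
#' @param config A [scenario_config()].
#' @return A list with `fields` (named list of [generate_inclusion_field()]
#'   results, names `group.fieldNN`) and `manifest` (tibble: `field_id`,
#'   `group`, `seed`, true live/condensed nucleus and particle counts).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_total <- length(config$groups) * config$n_fields
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  fields <- list()
  rows <- list()
  idx <- 0L
  for (g in names(config$groups)) {
    for (i in seq_len(config$n_fields)) {
      idx <- idx + 1L
      spec <- config$base
      ov <- config$groups[[g]]
      if (length(ov)) spec <- do.call(inclusion_field_spec,
                                      modifyList(unclass_spec_args(spec), ov))
      spec$seed <- seeds[idx]
      fid <- sprintf("%s.field%02d", g, i)
      fields[[fid]] <- generate_inclusion_field(spec)
      tr <- fields[[fid]]$truth
      rows[[idx]] <- tibble::tibble(
        field_id = fid, group = g, seed = seeds[idx],
        n_live = sum(tr$nuclei$state == "live"),
        n_condensed = sum(tr$nuclei$state == "condensed"),
        n_particles = nrow(tr$particles))
    }
  }
  list(fields = fields, manifest = dplyr::bind_rows(rows), config = config)
}

# spec -> constructor argument list (drops derived entries)
unclass_spec_args <- function(spec) {
  keep <- intersect(names(spec), names(formals(inclusion_field_spec)))
  spec[keep]
}
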