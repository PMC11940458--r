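#' The eight semantic dimensions
#'
#' Canonical names of the eight semantic dimensions used by the exclusivity
#' analysis: introspective (INTRO), mental state (MENT_ST), quantitative
#' (QUANT), spatial (SPACE), social (SOC), moral (MOR), theoretical (THEOR)
#' and economic (ECO). Every downstream operation that consumes "the eight
#' dimensions" consumes exactly this set; the order here is the canonical
#' display order.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' semantic_dimensions()
semantic_dimensions <- function() {
  c("INTRO", "MENT_ST", "QUANT", "SPACE", "SOC", "MOR", "THEOR", "ECO")
}

#' Default variable registry
#'
#' The registry of the 15 rated variables: five psycholinguistic variables
#' (concreteness CNC, imageability IMG, familiarity FAM, semantic diversity
#' SEM_DIV, all on a 1-7 Likert scale, and age of acquisition AoA, a
#' nonnegative age in years), two affective variables (valence VAL and
#' arousal ARO on a 1-9 scale), and the eight semantic dimensions
#' ([semantic_dimensions()]) on a 1-7 scale.
#'
#' AoA is not a Likert scale: its `scale_min` is 0 and its `scale_max` is
#' `Inf` (no upper bound is enforced), and it is excluded from scale-bound
#' checks, careless-rater counting and exclusivity, but included in
#' aggregation, trimming and the correlation matrix.
#'
#' @return A tibble with columns `name`, `scale_min`, `scale_max`, `kind`
#'   (one of `"psycholinguistic"`, `"affective"`, `"semantic_dimension"`,
#'   `"age_numeric"`).
#' @export
#' @examples
#' default_registry()
default_registry <- function() {
  reg <- tibble(
    name = c(
      "CNC", "IMG", "FAM", "SEM_DIV", "AoA", "VAL", "ARO",
      semantic_dimensions()
    ),
    scale_min = c(1, 1, 1, 1, 0, 1, 1, rep(1, 8)),
    scale_max = c(7, 7, 7, 7, Inf, 9, 9, rep(7, 8)),
    kind = c(
      rep("psycholinguistic", 4), "age_numeric", rep("affective", 2),
      rep("semantic_dimension", 8)
    )
  )
  validate_registry(reg)
}

#' Validate a variable registry
#'
#' Checks that variable names are unique, scale bounds are ordered, and kinds
#' are known. Returns the registry invisibly unchanged so it can be piped.
#'
#' @param registry A data frame with columns `name`, `scale_min`,
#'   `scale_max`, `kind`.
#' @return The validated registry (a tibble).
#' @export
validate_registry <- function(registry) {
  assert_df(registry, "registry")
  assert_cols(registry, c("name", "scale_min", "scale_max", "kind"), "registry")
  if (anyDuplicated(registry$name)) {
    abort(sprintf(
      "Duplicate variable name(s) in registry: %s.",
      paste(unique(registry$name[duplicated(registry$name)]), collapse = ", ")
    ))
  }
  if (any(registry$scale_min >= registry$scale_max)) {
    bad <- registry$name[registry$scale_min >= registry$scale_max]
    abort(sprintf("scale_min must be < scale_max (violated by: %s).",
                  paste(bad, collapse = ", ")))
  }
  known <- c("psycholinguistic", "affective", "semantic_dimension", "age_numeric")
  if (!all(registry$kind %in% known)) {
    abort(sprintf("Unknown variable kind(s): %s.",
                  paste(setdiff(registry$kind, known), collapse = ", ")))
  }
  as_tibble(registry)
}

# Variables counted against Likert-scale rules (everything except ages).
likert_variables <- function(registry = default_registry()) {
  registry$name[registry$kind != "age_numeric"]
}

registry_dimensions <- function(registry = default_registry()) {
  dims <- registry$name[registry$kind == "semantic_dimension"]
  if (length(dims) == 0) abort("Registry contains no semantic dimensions.")
  dims
}

#' Serialize / read a variable registry as YAML
#'
#' @param registry A registry tibble (see [default_registry()]).
#' @param path File path. `write_registry()` writes YAML; `read_registry()`
#'   reads and validates it.
#' @return `read_registry()` returns the registry tibble; `write_registry()`
#'   returns `path` invisibly.
#' @export
write_registry <- function(registry, path) {
  registry <- validate_registry(registry)
  # Inf is not representable in YAML numbers portably; use the string ".inf"
  out <- purrr::pmap(registry, function(name, scale_min, scale_max, kind) {
    list(
      name = name, scale_min = scale_min,
      scale_max = if (is.infinite(scale_max)) ".inf" else scale_max,
      kind = kind
    )
  })
  yaml::write_yaml(list(variables = out), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$variables)) abort("Registry file has no `variables` block.")
  reg <- purrr::map_dfr(raw$variables, function(v) {
    tibble(
      name = v$name,
      scale_min = as.numeric(v$scale_min),
      scale_max = if (identical(v$scale_max, ".inf")) Inf else as.numeric(v$scale_max),
      kind = v$kind
    )
  })
  validate_registry(reg)
}
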