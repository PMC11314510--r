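#' Canonical registry of moss functional traits
#'
#' The fifteen functional traits used throughout the package, with their
#' measurement kind and units. Binary traits record presence/absence of a
#' structure; categorical traits carry a fixed two-level attribute grouping
#' (first level = reference); continuous traits are non-negative lengths or
#' counts.
#'
#' The traits are: plant sex, sporophyte presence, vegetative reproduction,
#' capsule length, capsule shape, capsule on seta, seta length, seta shape,
#' spore diameter, spore shape, spore ornamentation, persistent protonema,
#' leaf length, stem length, and substrate breadth (the number of distinct
#' substrate types a species occupies).
#'
#' @return A data frame with one row per trait and columns `name` (column
#'   identifier), `label` (display name), `kind` (`"binary"`,
#'   `"categorical"` or `"continuous"`), `units`, and a list-column
#'   `attributes` holding the allowed category labels for categorical
#'   traits (first element is the reference level).
#' @export
#' @examples
#' reg <- moss_trait_registry()
#' nrow(reg)  # 15
moss_trait_registry <- function() {
  reg <- data.frame(
    name = c("plant_sex", "sporophyte_presence", "vegetative_reproduction",
             "capsule_length", "capsule_shape", "capsule_on_seta",
             "seta_length", "seta_shape", "spore_diameter", "spore_shape",
             "spore_ornamentation", "persistent_protonema", "leaf_length",
             "stem_length", "substrate_breadth"),
    label = c("Plant sex", "Sporophyte presence", "Vegetative reproduction",
              "Capsule length", "Capsule shape", "Capsule on seta",
              "Seta length", "Seta shape", "Spore diameter", "Spore shape",
              "Spore ornamentation", "Persistent protonema", "Leaf length",
              "Stem length", "Substrate breadth"),
    kind = c("categorical", "binary", "binary",
             "continuous", "categorical", "categorical",
             "continuous", "categorical", "continuous", "categorical",
             "categorical", "binary", "continuous",
             "continuous", "continuous"),
    units = c("", "", "", "mm", "", "", "mm", "", "um", "", "", "", "mm",
              "mm", "count"),
    stringsAsFactors = FALSE
  )
  reg$attributes <- list(
    c("dioicous", "monoicous"), NULL, NULL,
    NULL, c("ovoid", "cylindric"), c("erect", "pendent"),
    NULL, c("straight", "curved"), NULL, c("spherical", "ellipsoidal"),
    c("smooth", "papillose"), NULL, NULL, NULL, NULL
  )
  reg
}

#' @rdname moss_trait_registry
#' @details `sporophyte_morphology_traits()` returns the names of traits
#'   that describe the sporophyte itself (capsule, seta and spore traits).
#'   These are the traits that can only be recorded for sporophyte-bearing
#'   specimens and that define the second (sporophyte-morphology) model's
#'   candidate pool.
#' @export
sporophyte_morphology_traits <- function() {
  c("capsule_length", "capsule_shape", "capsule_on_seta",
    "seta_length", "seta_shape",
    "spore_diameter", "spore_shape", "spore_ornamentation")
}

# binary presence-type traits subject to empty-cell = absence imputation
presence_type_traits <- function() {
  c("sporophyte_presence", "vegetative_reproduction", "persistent_protonema")
}

registry_kind <- function(registry, trait) {
  i <- match(trait, registry$name)
  if (is.na(i)) stop("unknown trait: ", trait, call. = FALSE)
  registry$kind[i]
}

registry_attributes <- function(registry, trait) {
  i <- match(trait, registry$name)
  if (is.na(i)) stop("unknown trait: ", trait, call. = FALSE)
  registry$attributes[[i]]
}
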