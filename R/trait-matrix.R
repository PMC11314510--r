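#' Species-by-trait matrix for extinction-risk modeling
#'
#' A `trait_matrix` holds one row per species: the species name, its IUCN
#' Red List category, the binarized threat status, and one column per
#' registered functional trait. Continuous traits may be stored raw or as
#' z-scores; applied scaling parameters are kept alongside so raw-unit
#' inputs can be scored later.
#'
#' @param data A data frame with columns `species`, `iucn_category` and one
#'   column per trait present (names from [moss_trait_registry()]).
#' @param registry Trait registry data frame; defaults to the canonical
#'   15-trait registry.
#' @return An object of class `trait_matrix`: a list with elements `data`
#'   (the validated data frame, plus a `threat_status` column in
#'   `{"0","1","DD"}`), `registry`, `scaling` (named list of
#'   `c(mean, sd)` per z-scaled continuous trait) and `log` (parse and
#'   imputation bookkeeping).
#' @export
trait_matrix <- function(data, registry = moss_trait_registry()) {
  stopifnot(is.data.frame(data))
  if (!all(c("species", "iucn_category") %in% names(data))) {
    stop("data must have 'species' and 'iucn_category' columns", call. = FALSE)
  }
  if (anyDuplicated(data$species)) {
    stop("duplicated species names: ",
         paste(unique(data$species[duplicated(data$species)]), collapse = ", "),
         call. = FALSE)
  }
  data$threat_status <- binarize_status(data$iucn_category)
  tm <- structure(
    list(data = data, registry = registry, scaling = list(),
         log = list(imputed = integer(), parsed_ranges = 0L)),
    class = "trait_matrix"
  )
  tm
}

#' @export
print.trait_matrix <- function(x, ...) {
  st <- status_counts(x)
  cat("Species x trait matrix: ", nrow(x$data), " species\n", sep = "")
  cat("  threatened: ", st[["1"]], "  non-threatened: ", st[["0"]],
      "  DD: ", st[["DD"]], "\n", sep = "")
  tr <- intersect(x$registry$name, names(x$data))
  cat("  traits recorded: ", length(tr), "\n", sep = "")
  if (length(x$scaling)) {
    cat("  z-scaled: ", paste(names(x$scaling), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) {
  c(nrow(x$data), length(intersect(x$registry$name, names(x$data))))
}

#' Count species by binarized threat status
#'
#' @param tm A [trait_matrix()].
#' @return Named integer vector with elements `"1"` (threatened), `"0"`
#'   (non-threatened) and `"DD"`; the three counts sum to the number of
#'   species.
#' @export
status_counts <- function(tm) {
  s <- factor(tm$data$threat_status, levels = c("1", "0", "DD"))
  tab <- table(s)
  c("1" = unname(tab[["1"]]), "0" = unname(tab[["0"]]), DD = unname(tab[["DD"]]))
}

#' Binarize IUCN Red List categories into threat status
#'
#' Extinct (EX), Critically Endangered (CR), Endangered (EN) and Vulnerable
#' (VU) species are labeled threatened (`"1"`); Near Threatened (NT) and
#' Least Concern (LC) species non-threatened (`"0"`). Data Deficient (DD)
#' species keep the label `"DD"`: they are excluded from model fitting and
#' retained as the triage prediction set.
#'
#' @param category Character vector of IUCN category codes.
#' @return Character vector in `{"1", "0", "DD"}`, same length as input.
#' @export
#' @examples
#' binarize_status(c("VU", "NT", "DD"))
binarize_status <- function(category) {
  category <- toupper(trimws(as.character(category)))
  known <- c(EX = "1", CR = "1", EN = "1", VU = "1", NT = "0", LC = "0",
             DD = "DD")
  bad <- setdiff(unique(category), names(known))
  if (length(bad)) {
    stop("unrecognized IUCN category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(known[category])
}

#' Derive substrate breadth from a list of substrate labels
#'
#' Substrate breadth is the number of distinct substrate types a species has
#' been recorded occupying, with equal weighting for all substrates.
#' Duplicated labels collapse; label order is irrelevant. An empty record
#' yields a missing value (never zero), since absence of substrate data is
#' not evidence of a zero-breadth niche.
#'
#' @param substrates Character vector of substrate labels for one species,
#'   or a single `|`-separated string.
#' @param vocabulary Optional controlled vocabulary; labels outside it
#'   trigger a warning but are still counted.
#' @return Integer count of distinct substrates, or `NA` for an empty list.
#' @export
#' @examples
#' derive_substrate_breadth(c("rock", "soil", "bark"))  # 3
#' derive_substrate_breadth("rock|rock")                # 1
derive_substrate_breadth <- function(substrates, vocabulary = NULL) {
  if (length(substrates) == 1 && is.character(substrates) &&
      grepl("|", substrates, fixed = TRUE)) {
    substrates <- strsplit(substrates, "|", fixed = TRUE)[[1]]
  }
  substrates <- trimws(substrates)
  substrates <- substrates[!is.na(substrates) & nzchar(substrates)]
  if (!length(substrates)) {
    warning("empty substrate list: breadth recorded as missing", call. = FALSE)
    return(NA_integer_)
  }
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(substrates), vocabulary)
    if (length(unknown)) {
      warning("substrate labels outside vocabulary: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  length(unique(substrates))
}

# Parse one continuous cell: "", NA -> NA; "a-b" or "a–b" range -> midpoint.
parse_continuous_cell <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || !nzchar(x)) return(NA_real_)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  parts <- strsplit(x, "–|—|(?<=[0-9])-", perl = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) == 2 && !anyNA(vals)) return(mean(vals))
  stop("cannot parse continuous value: '", x, "'", call. = FALSE)
}

#' Read a species trait matrix from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and columns
#' `species`, `iucn_category`, then one column per trait; empty cells
#' (`""`) are missing. Continuous cells may hold a printed range
#' (`"4-8"`), which is stored as its midpoint. A `substrates` column of
#' `|`-separated labels, when present, is converted to the
#' `substrate_breadth` count.
#'
#' @param path Path to the CSV file.
#' @param registry Trait registry; columns outside
#'   `species`/`iucn_category`/`substrates`/registry names are rejected or
#'   warned about according to `unknown`.
#' @param unknown `"warn"` (default) or `"error"` for unknown columns.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, registry = moss_trait_registry(),
                              unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL,
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- c("species", "iucn_category", "substrates", registry$name)
  extra <- setdiff(names(raw), expected)
  if (length(extra)) {
    msg <- paste("unknown columns:", paste(extra, collapse = ", "))
    if (unknown == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  if (!all(c("species", "iucn_category") %in% names(raw))) {
    stop("CSV must have 'species' and 'iucn_category' columns", call. = FALSE)
  }
  n_ranges <- 0L
  out <- data.frame(species = raw$species, iucn_category = raw$iucn_category,
                    stringsAsFactors = FALSE)
  if ("substrates" %in% names(raw) && !"substrate_breadth" %in% names(raw)) {
    out$substrate_breadth <- vapply(raw$substrates, function(s) {
      if (!nzchar(trimws(s))) NA_real_
      else as.numeric(suppressWarnings(derive_substrate_breadth(s)))
    }, numeric(1), USE.NAMES = FALSE)
  }
  for (trait in intersect(registry$name, names(raw))) {
    kind <- registry_kind(registry, trait)
    col <- raw[[trait]]
    if (kind == "continuous") {
      vals <- vapply(seq_along(col), function(i) {
        v <- tryCatch(parse_continuous_cell(col[i]),
                      error = function(e) stop("row ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
        v
      }, numeric(1))
      n_ranges <- n_ranges + sum(!is.na(vals) &
                                   is.na(suppressWarnings(as.numeric(col))))
      out[[trait]] <- vals
    } else {
      v <- trimws(col)
      v[!nzchar(v)] <- NA_character_
      attrs <- registry_attributes(registry, trait)
      allowed <- if (kind == "binary") c("present", "absent") else attrs
      bad <- setdiff(unique(v[!is.na(v)]), allowed)
      if (length(bad)) {
        stop("trait '", trait, "': unexpected value(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      out[[trait]] <- v
    }
  }
  tm <- trait_matrix(out, registry)
  tm$log$parsed_ranges <- n_ranges
  tm
}

#' Write a trait matrix to CSV with a JSON sidecar
#'
#' The sidecar records scaling parameters and parse/imputation logs so a
#' written matrix round-trips exactly (values and missingness) through
#' [read_trait_matrix()].
#'
#' @param tm A [trait_matrix()].
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_trait_matrix <- function(tm, path) {
  df <- tm$data
  df$threat_status <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  side <- list(scaling = tm$scaling, log = tm$log)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Impute absence for missing binary presence-type traits
#'
#' Taxonomic descriptions report only the presence of structures such as
#' sporophytes, vegetative propagules or persistent protonemata, so an
#' empty cell for these binary traits is read as absence of the structure.
#' Continuous and categorical missing cells are untouched.
#'
#' @param tm A [trait_matrix()].
#' @return The matrix with missing binary presence-type cells set to
#'   `"absent"`; imputation counts per trait are appended to `tm$log$imputed`.
#' @export
impute_binary_absence <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  for (trait in intersect(presence_type_traits(), names(tm$data))) {
    miss <- is.na(tm$data[[trait]])
    tm$data[[trait]][miss] <- "absent"
    tm$log$imputed[trait] <- sum(miss)
  }
  tm
}

#' z-scale a continuous trait
#'
#' Replaces stored values of a continuous trait with z-scores
#' `(x - mean) / sd` and records the parameters in `tm$scaling` so raw-unit
#' inputs can be scored later. When estimating from data, the mean and
#' sample standard deviation (n - 1 denominator) are computed from
#' non-missing values of non-DD records only: DD species are the
#' prediction set and never inform the scaling.
#'
#' @param tm A [trait_matrix()].
#' @param trait Name of a continuous trait present in the matrix.
#' @param params Either `"estimate"` or a numeric vector `c(mean, sd)`.
#' @return The matrix with the trait column z-scaled.
#' @export
zscale <- function(tm, trait, params = "estimate") {
  stopifnot(inherits(tm, "trait_matrix"))
  if (registry_kind(tm$registry, trait) != "continuous") {
    stop("zscale applies to continuous traits only: ", trait, call. = FALSE)
  }
  if (trait %in% names(tm$scaling)) {
    stop("trait already z-scaled: ", trait, call. = FALSE)
  }
  x <- tm$data[[trait]]
  if (identical(params, "estimate")) {
    use <- x[tm$data$threat_status != "DD" & !is.na(x)]
    params <- c(mean = mean(use), sd = stats::sd(use))
  } else {
    params <- c(mean = unname(params[1]), sd = unname(params[2]))
  }
  if (!is.finite(params["sd"]) || params["sd"] <= 0) {
    stop("degenerate trait '", trait, "': sd must be > 0", call. = FALSE)
  }
  tm$data[[trait]] <- (x - params[["mean"]]) / params[["sd"]]
  tm$scaling[[trait]] <- params
  tm
}

#' Invert the z-scaling of a continuous trait
#'
#' @param tm A [trait_matrix()] whose `trait` has been z-scaled.
#' @param trait Trait name.
#' @return The matrix with raw-unit values restored and the scaling entry
#'   removed.
#' @export
zscale_invert <- function(tm, trait) {
  p <- tm$scaling[[trait]]
  if (is.null(p)) stop("trait not z-scaled: ", trait, call. = FALSE)
  tm$data[[trait]] <- tm$data[[trait]] * p[["sd"]] + p[["mean"]]
  tm$scaling[[trait]] <- NULL
  tm
}

#' Flag species with recorded sporophyte morphology
#'
#' `TRUE` for records where at least one capsule, seta or spore trait is
#' recorded; only these species can be scored by the sporophyte-morphology
#' model (MAM2).
#'
#' @param tm A [trait_matrix()].
#' @return Logical vector, one element per species.
#' @export
has_sporophyte_traits <- function(tm) {
  cols <- intersect(sporophyte_morphology_traits(), names(tm$data))
  if (!length(cols)) return(rep(FALSE, nrow(tm$data)))
  Reduce(`|`, lapply(cols, function(cl) !is.na(tm$data[[cl]])))
}
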