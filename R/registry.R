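#' @include AllGenerics.R
NULL

#' Convert kJ/mol to kcal/mol
#'
#' The thermochemical calorie convention: values in kJ/mol are divided by
#' 4.184. Full precision is retained; rounding for display is a formatting
#' concern (see [formatTable()]).
#'
#' @param x numeric vector in kJ/mol.
#' @return numeric vector in kcal/mol.
#' @examples
#' kjToKcal(124.7)  # 29.80...
#' @export
kjToKcal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x) | is.na(x)))
  x / 4.184
}

# Accept the Unicode minus (U+2212) on numeric input; canonical output ASCII.
.asNumber <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("−", "-", trimws(as.character(x)))
  x[x %in% c("", "NA", "-")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("non-numeric value: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  out
}

.emptySpecies <- function()
  data.frame(id = character(0), name = character(0), formula = character(0),
             charge = integer(0), unpaired_electrons = integer(0),
             stringsAsFactors = FALSE)

.emptyProperties <- function()
  data.frame(species_id = character(0), quantity = character(0),
             method = character(0), value = numeric(0), unit = character(0),
             uncertainty = numeric(0), source = character(0),
             stringsAsFactors = FALSE)

#' Build a registry from in-memory data frames
#'
#' Validates, canonicalizes units (kJ/mol converted to kcal/mol on entry) and
#' returns a [ThermoRegistry-class]. Duplicate \code{(species, quantity,
#' method)} keys are rejected.
#'
#' @param species data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{charge}, \code{unpaired_electrons}.
#' @param properties data.frame with columns \code{species_id},
#'   \code{quantity}, \code{method}, \code{value}, \code{unit},
#'   \code{uncertainty}, \code{source}; \code{unit} must be one of
#'   \code{"kcal/mol"}, \code{"kJ/mol"}, \code{"cm-1"}, \code{"angstrom"},
#'   \code{"debye"}.
#' @param elements allowed element universe.
#' @return a \code{ThermoRegistry}.
#' @export
registryFromFrames <- function(species, properties = .emptyProperties(),
                               elements = .DEFAULT_UNIVERSE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  properties <- as.data.frame(properties, stringsAsFactors = FALSE)
  if (nrow(species)) {
    species$id <- as.character(species$id)
    species$name <- as.character(species$name)
    species$formula <- as.character(species$formula)
    species$charge <- as.integer(.asNumber(species$charge))
    species$unpaired_electrons <- as.integer(.asNumber(species$unpaired_electrons))
  } else species <- .emptySpecies()
  if (nrow(properties)) {
    properties$species_id <- as.character(properties$species_id)
    properties$quantity <- as.character(properties$quantity)
    properties$method <- as.character(properties$method)
    properties$value <- .asNumber(properties$value)
    properties$unit <- as.character(properties$unit)
    properties$uncertainty <- .asNumber(properties$uncertainty)
    properties$source <- as.character(properties$source)
    known <- c("kcal/mol", "kJ/mol", "cm-1", "angstrom", "debye")
    bad <- !properties$unit %in% known
    if (any(bad))
      stop("unknown unit: ", paste(unique(properties$unit[bad]), collapse = ", "),
           call. = FALSE)
    kj <- properties$unit == "kJ/mol"
    properties$value[kj] <- kjToKcal(properties$value[kj])
    properties$uncertainty[kj] <- kjToKcal(properties$uncertainty[kj])
    properties$unit[kj] <- "kcal/mol"
    if (any(!is.na(properties$uncertainty) & properties$uncertainty < 0))
      stop("negative uncertainty", call. = FALSE)
  } else properties <- .emptyProperties()
  rownames(species) <- NULL
  rownames(properties) <- NULL
  methods::new("ThermoRegistry", species = species, properties = properties,
               elements = elements)
}

.readTable <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) return(NULL)
    df <- jsonlite::fromJSON(txt)
    if (is.null(df) || (is.list(df) && !length(df))) return(NULL)
    as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) character(0))
    if (!length(first) || !nzchar(trimws(first))) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
}

#' Load a species/property registry from fixture files
#'
#' Reads the CSV or JSON interchange schema (identical field names in both;
#' the two readers produce identical registries from equivalent content) and
#' returns a validated [ThermoRegistry-class]. An empty file yields an empty
#' registry with a warning. Record counts are reported via \code{message()}.
#'
#' @param speciesPath path to the species file (\code{.csv} or \code{.json}).
#' @param propertyPath path to the property file; may be \code{NULL} for a
#'   species-only registry.
#' @param elements allowed element universe.
#' @param quiet suppress the record-count message.
#' @return a \code{ThermoRegistry}.
#' @examples
#' reg <- exampleRegistry()
#' lookupProperty(reg, "pyridine", "dHf_gas", "experimental")$value  # 33.6
#' @export
loadRegistry <- function(speciesPath, propertyPath = NULL,
                         elements = .DEFAULT_UNIVERSE, quiet = FALSE) {
  sp <- .readTable(speciesPath)
  if (is.null(sp)) {
    warning("empty species file: ", speciesPath, call. = FALSE)
    sp <- .emptySpecies()
  }
  pr <- NULL
  if (!is.null(propertyPath)) {
    pr <- .readTable(propertyPath)
    if (is.null(pr)) {
      warning("empty property file: ", propertyPath, call. = FALSE)
      pr <- .emptyProperties()
    }
  } else pr <- .emptyProperties()
  reg <- registryFromFrames(sp, pr, elements)
  if (!quiet)
    message("loaded ", nrow(reg@species), " species and ",
            nrow(reg@properties), " property records")
  reg
}

#' Write a registry back to CSV or JSON
#'
#' Inverse of [loadRegistry()]; a save/load round trip is lossless.
#'
#' @param registry a [ThermoRegistry-class].
#' @param speciesPath,propertyPath output paths; format chosen by extension
#'   (\code{.csv} or \code{.json}).
#' @return invisibly, the registry.
#' @export
writeRegistry <- function(registry, speciesPath, propertyPath) {
  .writeTable <- function(df, path) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           na = "null", pretty = TRUE)
    } else {
      utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    }
  }
  .writeTable(registry@species, speciesPath)
  .writeTable(registry@properties, propertyPath)
  invisible(registry)
}

#' @rdname ThermoRegistry-class
#' @export
setMethod("speciesTable", "ThermoRegistry", function(x) x@species)

#' @rdname ThermoRegistry-class
#' @export
setMethod("propertyTable", "ThermoRegistry", function(x) x@properties)

#' @rdname ThermoRegistry-class
#' @export
setMethod("elementUniverse", "ThermoRegistry", function(x) x@elements)

#' @rdname lookupProperty
#' @export
setMethod("lookupProperty", "ThermoRegistry",
  function(x, species, quantity, method) {
    pr <- x@properties
    hit <- pr$species_id == species & pr$quantity == quantity & pr$method == method
    if (!any(hit))
      stop("no record for species '", species, "', quantity '", quantity,
           "', method '", method, "'", call. = FALSE)
    i <- which(hit)[1L]
    list(value = pr$value[i], uncertainty = pr$uncertainty[i],
         unit = pr$unit[i], source = pr$source[i])
  })

# Composition of a registered species, as a named integer vector.
.speciesComposition <- function(registry, id) {
  sp <- registry@species
  i <- match(id, sp$id)
  if (is.na(i)) stop("unknown species id: ", id, call. = FALSE)
  parseFormula(sp$formula[i], registry@elements)
}

.speciesField <- function(registry, id, field) {
  i <- match(id, registry@species$id)
  if (anyNA(i)) stop("unknown species id: ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  registry@species[[field]][i]
}

setMethod("show", "ThermoRegistry", function(object) {
  cat("ThermoRegistry with", nrow(object@species), "species and",
      nrow(object@properties), "property records\n")
  cat("  elements:", paste(object@elements, collapse = " "), "\n")
  if (nrow(object@properties)) {
    m <- sort(unique(object@properties$method))
    cat("  methods: ", paste(m, collapse = ", "), "\n", sep = "")
    q <- table(object@properties$quantity)
    cat("  quantities: ",
        paste(names(q), "(", as.integer(q), ")", sep = "", collapse = ", "),
        "\n", sep = "")
  }
  invisible(NULL)
})
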