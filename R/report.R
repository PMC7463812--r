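#' @include synthetic.R
NULL

.readNumericCsv <- function(path, numericCols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in intersect(numericCols, names(df))) df[[col]] <- .asNumber(df[[col]])
  df
}

#' Load a BDE / -TTRS scale fixture table
#'
#' @param path CSV with columns \code{species_id}, \code{method},
#'   \code{bde}, \code{neg_ttrs} (empty cells for values not on record).
#' @return data.frame suitable for [auditScale()].
#' @export
loadScaleTable <- function(path) {
  .readNumericCsv(path, c("bde", "neg_ttrs"))
}

#' Load a hydrogenation step-enthalpy fixture table
#'
#' @param path CSV with columns \code{scheme}, \code{method}, \code{dh1},
#'   \code{dh2}, \code{dh3}, \code{total}.
#' @return data.frame.
#' @export
loadStepTable <- function(path) {
  .readNumericCsv(path, c("dh1", "dh2", "dh3", "total"))
}

#' Load the oxygen-transfer model-comparison fixture table
#'
#' Per computational model: the oxygen-transfer reaction enthalpy between
#' the two reference N-oxides and both oxides' BDEs.
#'
#' @param path CSV with columns \code{method}, \code{dE_r}, \code{dH_r},
#'   \code{bde_pno}, \code{bde_tmao}.
#' @return data.frame.
#' @export
loadModelTable <- function(path) {
  .readNumericCsv(path, c("dE_r", "dH_r", "bde_pno", "bde_tmao"))
}

#' Render a result table
#'
#' Display rounding for enthalpy tables is one decimal (0.1 kcal/mol);
#' internal computation always keeps full precision, so rounding here is
#' purely presentational.
#'
#' @param df data.frame.
#' @param format \code{"data.frame"} (rounded copy), \code{"csv"},
#'   \code{"markdown"} or \code{"json"} (character output for the last
#'   three).
#' @param digits decimals for numeric columns.
#' @return data.frame or character vector.
#' @export
formatTable <- function(df, format = c("data.frame", "csv", "markdown", "json"),
                        digits = 1L) {
  format <- match.arg(format)
  out <- df
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], round, digits = digits)
  switch(format,
    "data.frame" = out,
    "csv" = {
      con <- textConnection("csvOut", "w", local = TRUE)
      utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
      close(con)
      csvOut
    },
    "markdown" = {
      cells <- vapply(seq_len(ncol(out)), function(j)
        max(nchar(c(names(out)[j], format(out[[j]], trim = TRUE)))),
        numeric(1L))
      pad <- function(x, w) formatC(x, width = w, flag = "-")
      header <- paste0("| ", paste(mapply(pad, names(out), cells),
                                   collapse = " | "), " |")
      sep <- paste0("|", paste(vapply(cells + 2, function(w)
        paste(rep("-", w), collapse = ""), character(1L)), collapse = "|"), "|")
      rows <- vapply(seq_len(nrow(out)), function(i) {
        vals <- vapply(seq_len(ncol(out)), function(j)
          pad(format(out[[j]][i], trim = TRUE), cells[j]), character(1L))
        paste0("| ", paste(vals, collapse = " | "), " |")
      }, character(1L))
      c(header, sep, rows)
    },
    "json" = jsonlite::toJSON(out, dataframe = "rows", digits = NA,
                              pretty = TRUE, na = "null"))
}

#' Audit report over a scale fixture
#'
#' Thin reporting wrapper around [auditScale()]: per-method oxygen gaps and
#' the flagged rows, optionally restricted to one method.
#'
#' @param scale data.frame as for [auditScale()] (default: the packaged
#'   dissociation-scale fixture).
#' @param tolerance flagging threshold, kcal/mol.
#' @param method optional single method tag to restrict to.
#' @return list with \code{methods}, \code{outliers} and \code{clean}
#'   (\code{TRUE} iff no outliers).
#' @export
auditReport <- function(scale = loadScaleTable(fixturePath("scale_table3.csv")),
                        tolerance = 0.2, method = NULL) {
  if (!is.null(method)) {
    scale <- scale[scale$method == method, , drop = FALSE]
    if (!nrow(scale)) stop("no scale rows for method '", method, "'",
                           call. = FALSE)
  }
  a <- auditScale(scale, tolerance)
  c(a, list(clean = nrow(a$outliers) == 0L))
}

# Isomer sets and oxide pairs used by the packaged report tables.
.LADDER_SETS <- list(
  nitro = c("nitromethane", "methyl_nitrite"),
  aminol = c("dimethylaminomethanol", "tmao"),
  pyridinol = c("hydroxypyridine_2", "pyridone_2", "pno"))

#' Regenerate the package's derived report tables
#'
#' Recomputes, from a registry and the packaged fixtures, the derived tables
#' of the N-oxide thermochemistry analysis: isomer ladders, the
#' model-comparison consistency table (oxygen-transfer enthalpy vs BDE
#' difference), the experimental dissociation scale, proton-affinity
#' differences, and hydrogenation step sums. Output is deterministic for a
#' given registry and fixtures. Each table carries its consistency check;
#' the \code{ok} element is \code{TRUE} iff all checks pass.
#'
#' @param registry a [ThermoRegistry-class] (default: packaged fixtures).
#' @param which subset of \code{c("ladders", "models", "scale", "pa",
#'   "hydrogenation")}.
#' @param methods method tags for the ladder/hydrogenation tables.
#' @param format output format passed to [formatTable()] for the rendered
#'   copies.
#' @return list with one element per requested table (each a list of
#'   \code{table}, \code{rendered}, \code{ok}) plus overall \code{ok}.
#' @export
runTables <- function(registry = exampleRegistry(),
                      which = c("ladders", "models", "scale", "pa",
                                "hydrogenation"),
                      methods = c("experimental", "B3LYP/6-31G*",
                                  "M06/6-311G+(d,p)"),
                      format = "data.frame") {
  which <- match.arg(which, several.ok = TRUE)
  out <- list()

  if ("ladders" %in% which) {
    rows <- do.call(rbind, lapply(names(.LADDER_SETS), function(set) {
      ids <- .LADDER_SETS[[set]]
      do.call(rbind, lapply(methods, function(m) {
        lad <- isomerLadder(registry, ids, m)
        data.frame(set = set, method = m, species = ids,
                   rel_dHf = unname(lad), stringsAsFactors = FALSE)
      }))
    }))
    out$ladders <- list(table = rows,
                        rendered = formatTable(rows, format), ok = TRUE)
  }

  if ("models" %in% which) {
    models <- loadModelTable(fixturePath("table2.csv"))
    models$bde_diff <- models$bde_pno - models$bde_tmao
    models$consistent <- abs(models$bde_diff + models$dH_r) <= 0.15
    out$models <- list(table = models,
                       rendered = formatTable(models, format),
                       ok = all(models$consistent))
  }

  if ("scale" %in% which) {
    pairs <- utils::read.csv(fixturePath("oxide_pairs.csv"),
                             stringsAsFactors = FALSE)
    sc <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      data.frame(species_id = pairs$oxide[i], method = "experimental",
                 bde = bde(registry, pairs$oxide[i], pairs$parent[i],
                           "experimental"),
                 neg_ttrs = negTTRS(registry, pairs$oxide[i],
                                    pairs$parent[i], "experimental"),
                 stringsAsFactors = FALSE)))
    audit <- auditScale(sc)
    out$scale <- list(table = sc, rendered = formatTable(sc, format),
                      audit = audit, ok = nrow(audit$outliers) == 0L)
  }

  if ("pa" %in% which) {
    dpa <- do.call(rbind, lapply(methods, function(m)
      data.frame(method = m, delta_pa = deltaPA(registry, "tmao", "pno", m),
                 stringsAsFactors = FALSE)))
    out$pa <- list(table = dpa, rendered = formatTable(dpa, format), ok = TRUE)
  }

  if ("hydrogenation" %in% which) {
    rows <- do.call(rbind, unlist(lapply(schemeIds(), function(sc)
      lapply(methods, function(m) {
        hs <- tryCatch(hydrogenationSequence(registry, sc, m),
                       error = function(e) NULL)
        if (is.null(hs)) return(NULL)  # no experimental chain for the N-oxide
        data.frame(scheme = sc, method = m, dh1 = hs$steps[["dH1"]],
                   dh2 = hs$steps[["dH2"]], dh3 = hs$steps[["dH3"]],
                   total = hs$total, stringsAsFactors = FALSE)
      })), recursive = FALSE))
    rows$sum_ok <- abs(rows$total - (rows$dh1 + rows$dh2 + rows$dh3)) <= 0.05
    out$hydrogenation <- list(table = rows,
                              rendered = formatTable(rows, format),
                              ok = all(rows$sum_ok))
  }

  out$ok <- all(vapply(out, function(x)
    if (is.list(x) && !is.null(x$ok)) x$ok else TRUE, logical(1L)))
  out
}
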