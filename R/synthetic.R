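#' @include estimators.R
NULL

# Run expr with a temporary RNG state seeded by `seed`; the caller's RNG
# state is restored afterwards (no global side effects).
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Element reference species (formation-enthalpy zero by convention).
.ELEMENT_REFS <- data.frame(
  id = c("el_c", "el_h2", "el_n2", "el_o2"),
  name = c("carbon reference", "dihydrogen", "dinitrogen", "dioxygen"),
  formula = c("C", "H2", "N2", "O2"),
  charge = 0L,
  unpaired_electrons = c(2L, 0L, 0L, 2L),
  stringsAsFactors = FALSE)

.atomCount <- function(comp) sum(comp)

# Random neutral closed-shell composition over C/H/N/O with consistent
# electron parity (H + N must be even for zero unpaired electrons).
.randomComposition <- function() {
  repeat {
    nc <- sample(0:6, 1L); nn <- sample(0:2, 1L); no <- sample(0:3, 1L)
    nh <- sample(0:12, 1L)
    if ((nh + nn) %% 2L != 0L) nh <- nh + 1L
    comp <- c(C = nc, H = nh, N = nn, O = no)
    comp <- comp[comp > 0L]
    if (length(comp)) return(comp)
  }
}

#' Generate a synthetic thermochemical network with known ground truth
#'
#' Builds a registry of random C/H/N/O species with known true formation
#' enthalpies, measurement records per pseudo-method, and exactly balanced
#' random reactions whose true reaction enthalpies are stored alongside.
#' Balance is guaranteed by construction: each reaction is a random integer
#' combination of species formation reactions, closed with element reference
#' species (\code{el_c}, \code{el_h2}, \code{el_n2}, \code{el_o2}; half-unit
#' rational coefficients arise naturally from the diatomic references).
#'
#' Pseudo-method records are \code{truth + offset * natoms + noise}: the
#' offset emulates a per-atom scale shift of a computational model, which
#' cancels exactly in balanced reactions, so noise-free records of every
#' method reproduce the ground-truth reaction enthalpies to machine
#' precision. Noise, when requested, perturbs measurement records only,
#' never the stored truth.
#'
#' @param nSpecies number of non-reference species (>= 2).
#' @param nReactions number of random balanced reactions (>= 1).
#' @param noiseSd Gaussian noise sd applied to measurement records
#'   (kcal/mol; 0 = noise-free).
#' @param methodOffsets named numeric: per-atom offset of each
#'   pseudo-method.
#' @param seed integer seed; the generator is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return a [SyntheticNetwork-class].
#' @examples
#' nw <- generateNetwork(10, 20, seed = 1)
#' r <- nw@reactions[[1]]
#' all.equal(reactionEnthalpy(r, nw@registry, "pseudo-exp"),
#'           unname(nw@reactionTruth[r@id]))
#' @export
generateNetwork <- function(nSpecies = 20L, nReactions = 50L, noiseSd = 0,
                            methodOffsets = c("pseudo-exp" = 0,
                                              "pseudo-dft" = 0.37),
                            seed = 1L) {
  stopifnot(nSpecies >= 2L, nReactions >= 1L, noiseSd >= 0,
            length(methodOffsets) >= 1L, !is.null(names(methodOffsets)))
  .withSeed(seed, {
    comps <- replicate(nSpecies, .randomComposition(), simplify = FALSE)
    ids <- sprintf("syn%03d", seq_len(nSpecies))
    species <- rbind(.ELEMENT_REFS,
                     data.frame(id = ids, name = ids,
                                formula = vapply(comps, formulaString,
                                                 character(1L)),
                                charge = 0L, unpaired_electrons = 0L,
                                stringsAsFactors = FALSE))
    truth <- stats::setNames(round(stats::runif(nSpecies, -80, 80), 3), ids)
    refComps <- lapply(.ELEMENT_REFS$formula, parseFormula)
    names(refComps) <- .ELEMENT_REFS$id
    allIds <- c(.ELEMENT_REFS$id, ids)
    allComps <- c(refComps, stats::setNames(comps, ids))
    allTruth <- c(stats::setNames(numeric(4L), .ELEMENT_REFS$id), truth)

    props <- do.call(rbind, lapply(names(methodOffsets), function(m) {
      vals <- allTruth + methodOffsets[[m]] *
        vapply(allComps, .atomCount, numeric(1L))
      if (noiseSd > 0) vals <- vals + stats::rnorm(length(vals), 0, noiseSd)
      data.frame(species_id = allIds, quantity = "dHf_gas", method = m,
                 value = as.numeric(vals), unit = "kcal/mol",
                 uncertainty = if (noiseSd > 0) noiseSd else NA_real_,
                 source = "synthetic", stringsAsFactors = FALSE)
    }))
    registry <- registryFromFrames(species, props)

    refOrder <- c(C = "el_c", H = "el_h2", N = "el_n2", O = "el_o2")
    refAtoms <- c(C = 1L, H = 2L, N = 2L, O = 2L)
    reactions <- vector("list", nReactions)
    rTruth <- numeric(nReactions)
    for (j in seq_len(nReactions)) {
      k <- sample(2:min(4L, nSpecies), 1L)
      pick <- sample(ids, k)
      coef <- sample(c(-3:-1, 1:3), k, replace = TRUE)
      net <- integer(0)
      for (i in seq_len(k))
        net <- .compCombine(net, allComps[[pick[i]]], coef[i])
      terms <- stats::setNames(lapply(coef, .rat), pick)
      for (e in names(refOrder)) {
        d <- if (e %in% names(net)) net[[e]] else 0L
        if (d != 0L)
          terms[[refOrder[[e]]]] <- .rat(-d, refAtoms[[e]])
      }
      reac <- list(); prod <- list()
      for (s in names(terms)) {
        co <- terms[[s]]
        if (co[1L] > 0L) prod[[s]] <- co else reac[[s]] <- .ratNeg(co)
      }
      rid <- sprintf("rxn%05d", j)
      reactions[[j]] <- methods::new("Reaction", id = rid, reactants = reac,
                                     products = prod, declaredClass = "plain")
      rTruth[j] <- sum(coef * truth[pick])
    }
    names(rTruth) <- vapply(reactions, function(r) r@id, character(1L))
    methods::new("SyntheticNetwork", registry = registry,
                 reactions = reactions, reactionTruth = rTruth,
                 speciesTruth = data.frame(id = ids, dHf_true = unname(truth),
                                           stringsAsFactors = FALSE),
                 methodOffsets = methodOffsets, seed = as.integer(seed))
  })
}

setMethod("show", "SyntheticNetwork", function(object) {
  cat("SyntheticNetwork (seed ", object@seed, "): ",
      nrow(object@speciesTruth), " species, ", length(object@reactions),
      " balanced reactions, methods: ",
      paste(names(object@methodOffsets), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' Replicate noisy measurements of one species
#'
#' Draws independent noisy measurements of a species' true formation
#' enthalpy (a replicate table, not a registry: registries key records
#' uniquely per species/quantity/method).
#'
#' @param network a [SyntheticNetwork-class].
#' @param species species id in the network.
#' @param n number of replicates.
#' @param noiseSd Gaussian measurement noise sd, kcal/mol.
#' @param seed integer seed.
#' @return data.frame with columns \code{species_id}, \code{replicate},
#'   \code{value}.
#' @export
generateReplicates <- function(network, species, n = 1000L, noiseSd = 0.5,
                               seed = 1L) {
  truth <- network@speciesTruth
  i <- match(species, truth$id)
  if (is.na(i)) stop("unknown synthetic species: ", species, call. = FALSE)
  .withSeed(seed, data.frame(
    species_id = species, replicate = seq_len(n),
    value = truth$dHf_true[i] + stats::rnorm(n, 0, noiseSd),
    stringsAsFactors = FALSE))
}

#' Generate a synthetic oxide family with planted BDE / -TTRS scales
#'
#' Creates \code{n} parent/oxide pairs (X, XO) and a scale table per
#' pseudo-method in which \code{bde - neg_ttrs} equals that method's planted
#' oxygen gap for every row, mirroring the structure of an N-oxide
#' dissociation scale. A registry is included whose \code{dHf_gas} records
#' (with per-method O-atom and O2 references) reproduce the same scale
#' through [bde()] and [negTTRS()]. Optionally one scale cell is corrupted,
#' for auditor tests.
#'
#' @param n number of (X, XO) pairs (>= 1).
#' @param gaps named numeric: planted O-atom gap per pseudo-method,
#'   kcal/mol.
#' @param seed integer seed.
#' @param corrupt \code{NULL}, or a list with elements \code{row} (pair
#'   index), \code{method}, \code{column} (\code{"bde"} or
#'   \code{"neg_ttrs"}) and \code{delta} (default +10) describing a single
#'   corrupted measurement cell.
#' @return list with \code{registry}, \code{pairs} (data.frame:
#'   \code{oxide}, \code{parent}), \code{scale} (data.frame as for
#'   [auditScale()]), \code{gaps}, \code{seed}.
#' @examples
#' fam <- generateOxideFamily(18, gaps = c(clean = 61.7), seed = 1)
#' auditScale(fam$scale)$methods  # gap 61.7, zero outliers
#' @export
generateOxideFamily <- function(n = 18L,
                                gaps = c("pseudo-exp" = 59.6,
                                         "pseudo-dft" = 61.7),
                                seed = 1L, corrupt = NULL) {
  stopifnot(n >= 1L, length(gaps) >= 1L, !is.null(names(gaps)))
  .withSeed(seed, {
    parents <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {  # parent must be oxidizable: keep O count below the cap
        comp <- .randomComposition()
        if (!("O" %in% names(comp)) || comp[["O"]] < 3L) break
      }
      parents[[i]] <- comp
    }
    pid <- sprintf("x%03d", seq_len(n))
    oid <- sprintf("x%03do", seq_len(n))
    oxComps <- lapply(parents, function(c) .compAdd(c, c(O = 1L)))
    parentTruth <- round(stats::runif(n, -60, 60), 3)
    # per pair and method: a BDE in a realistic 30-130 kcal/mol window
    bdeVals <- matrix(round(stats::runif(n * length(gaps), 30, 130), 3),
                      nrow = n)
    colnames(bdeVals) <- names(gaps)

    species <- data.frame(
      id = c("o_atom_3p", "o2", pid, oid),
      name = c("oxygen atom (3P)", "dioxygen", pid, oid),
      formula = c("O", "O2",
                  vapply(parents, formulaString, character(1L)),
                  vapply(oxComps, formulaString, character(1L))),
      charge = 0L,
      unpaired_electrons = c(2L, 2L, rep(0L, 2L * n)),
      stringsAsFactors = FALSE)

    props <- do.call(rbind, lapply(names(gaps), function(m) {
      g <- gaps[[m]]
      data.frame(
        species_id = c("o_atom_3p", "o2", pid, oid),
        quantity = "dHf_gas", method = m,
        value = c(g, 0, parentTruth, parentTruth + g - bdeVals[, m]),
        unit = "kcal/mol", uncertainty = NA_real_, source = "synthetic",
        stringsAsFactors = FALSE)
    }))
    registry <- registryFromFrames(species, props)

    scale <- do.call(rbind, lapply(names(gaps), function(m)
      data.frame(species_id = oid, method = m, bde = bdeVals[, m],
                 neg_ttrs = bdeVals[, m] - gaps[[m]],
                 stringsAsFactors = FALSE)))
    rownames(scale) <- NULL
    if (!is.null(corrupt)) {
      delta <- if (is.null(corrupt$delta)) 10 else corrupt$delta
      column <- if (is.null(corrupt$column)) "bde" else corrupt$column
      hit <- which(scale$species_id == oid[corrupt$row] &
                     scale$method == corrupt$method)
      scale[hit, column] <- scale[hit, column] + delta
    }
    list(registry = registry,
         pairs = data.frame(oxide = oid, parent = pid,
                            stringsAsFactors = FALSE),
         scale = scale, gaps = gaps, seed = as.integer(seed))
  })
}
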