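# Reaction/pathway library: JSON-backed store of the species universe, the
# shipped reaction stoichiometries and the named pathway compositions.

.nadphaxis_env <- new.env(parent = emptyenv())

# alternative spellings collapsed onto one canonical species id
.species_aliases <- c("NADP+" = "NADP", "FADH_2" = "FADH2", "NAD" = "NAD+",
                      "CoA" = "CoA", "beta-hydroxybutyrate" = "BHB")

canonical_species_id <- function(id) {
  hit <- match(id, names(.species_aliases))
  ifelse(is.na(hit), id, unname(.species_aliases[hit]))
}

#' Load a reaction/pathway library from JSON
#'
#' The JSON layout is the one the built-in library ships in
#' (\code{system.file("extdata", "reactions.json", package = "nadphaxis")}):
#' a \code{species} array (id, name, kind, optional \code{conjugate_of} and
#' \code{electrons_carried}), a \code{reactions} array whose \code{stoich}
#' maps species id to an integer or a \code{"num/den"} string (negative =
#' consumed), and a \code{pathways} array of \code{[id, multiplicity]} term
#' lists that may reference reactions or other pathways (nesting is allowed
#' to depth 3, cycles are rejected). Alternative cofactor spellings
#' (\code{NADP+}, \code{FADH_2}, \code{NAD}) are collapsed onto one canonical
#' id; a file that defines both spellings as distinct species is rejected.
#'
#' On load every reaction is checked for non-empty stoichiometry and for
#' conjugate-pair closure (for each cofactor pair, the consumed amount of one
#' member equals the produced amount of the other).
#'
#' @param path JSON file path.
#' @return an object of class \code{"axis_library"} with elements
#'   \code{species} (data.frame), \code{reactions} and \code{pathways}
#'   (named lists).
#' @export
load_reaction_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp_ids <- vapply(raw$species, function(s) canonical_species_id(s$id), character(1))
  if (anyDuplicated(sp_ids)) {
    dup <- unique(sp_ids[duplicated(sp_ids)])
    stop("species file distinguishes spellings that this package treats as one species: ",
         paste(dup, collapse = ", "))
  }
  species <- data.frame(
    id = sp_ids,
    name = vapply(raw$species, function(s) s$name %||% s$id, character(1)),
    kind = vapply(raw$species, function(s) s$kind %||% "carbon-metabolite", character(1)),
    conjugate_of = vapply(raw$species, function(s)
      if (is.null(s$conjugate_of)) NA_character_ else canonical_species_id(s$conjugate_of), character(1)),
    electrons_carried = vapply(raw$species, function(s)
      as.numeric(s$electrons_carried %||% 0), numeric(1)),
    stringsAsFactors = FALSE)
  .validate_species(species)

  reactions <- list()
  for (r in raw$reactions) {
    st <- r$stoich
    if (length(st) == 0L) stop("reaction '", r$id, "' has empty stoichiometry")
    ids <- canonical_species_id(names(st))
    unknown <- setdiff(ids, species$id)
    if (length(unknown))
      stop("reaction '", r$id, "' uses unknown species: ", paste(unknown, collapse = ", "))
    amt <- rat(vapply(st, function(v) as.character(v), character(1)))
    reactions[[r$id]] <- list(
      id = r$id, name = r$name %||% r$id,
      ledger = ledger(ids, amt),
      enzymes = unlist(r$enzymes),
      compartment = r$compartment %||% "unassigned",
      pathway_tag = r$pathway_tag %||% NA_character_)
  }

  pathways <- list()
  for (p in raw$pathways) {
    ids <- vapply(p$terms, function(t) as.character(t[[1]]), character(1))
    mult <- if (length(p$terms))
      rat(vapply(p$terms, function(t) as.character(t[[2]]), character(1)))
    else rat(numeric(0), numeric(0))
    pathways[[p$id]] <- list(
      id = p$id, name = p$name %||% p$id,
      mode = p$mode %||% "idealized",
      unit = p$unit %||% "per_glucose",
      composition = composition(ids, mult))
  }

  lib <- structure(list(species = species, reactions = reactions,
                        pathways = pathways, source = path),
                   class = "axis_library")
  .validate_closure(lib)
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_species <- function(species) {
  for (i in seq_len(nrow(species))) {
    mate <- species$conjugate_of[i]
    if (is.na(mate)) {
      if (species$electrons_carried[i] > 0)
        stop("species '", species$id[i], "' carries electrons but has no conjugate partner")
      next
    }
    if (mate == species$id[i])
      stop("species '", species$id[i], "' is conjugate of itself")
    j <- match(mate, species$id)
    if (is.na(j) || !identical(species$conjugate_of[j], species$id[i]))
      stop("conjugate relation not symmetric for '", species$id[i], "'")
    if (species$electrons_carried[i] > 0 && species$electrons_carried[j] > 0)
      stop("both members of pair ", species$id[i], "/", mate, " carry electrons")
  }
  invisible(species)
}

.validate_closure <- function(lib) {
  for (r in lib$reactions) {
    res <- pair_closure_residuals(r$ledger, lib)
    bad <- res$pair[res$residual_numeric != 0]
    if (length(bad))
      stop("reaction '", r$id, "' violates conjugate-pair closure for: ",
           paste(bad, collapse = ", "))
  }
  invisible(lib)
}

#' The built-in axis library
#'
#' Loads (and caches) the reaction/pathway definitions shipped with the
#' package.
#'
#' @param path optional path to an alternative JSON library file.
#' @return an \code{axis_library}.
#' @export
axis_library <- function(path = NULL) {
  if (!is.null(path)) return(load_reaction_library(path))
  if (is.null(.nadphaxis_env$library)) {
    f <- system.file("extdata", "reactions.json", package = "nadphaxis")
    .nadphaxis_env$library <- load_reaction_library(f)
  }
  .nadphaxis_env$library
}

#' @export
print.axis_library <- function(x, ...) {
  cat("Axis reaction library: ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$pathways), " pathways\n",
      sep = "")
  invisible(x)
}

#' Compositions of reactions and pathways
#'
#' An ordered list of (id, multiplicity) terms over a library's reactions and
#' pathways. Multiplicities are positive exact rationals and may be
#' fractional, e.g. 1/8 of a palmitate cycle.
#'
#' @param ids character vector of reaction or pathway ids.
#' @param mults \code{\link{rat}} vector (or coercible) of positive
#'   multiplicities, recycled to \code{length(ids)}.
#' @return an object of class \code{"composition"}.
#' @export
composition <- function(ids = character(), mults = rat(numeric(0), numeric(0))) {
  mults <- rat(mults)
  if (length(mults) == 1L && length(ids) > 1L)
    mults <- .rat_new(rep(mults$num, length(ids)), rep(mults$den, length(ids)))
  stopifnot(is.character(ids), length(ids) == length(mults))
  if (length(mults) && any(!(mults > rat(0))))
    stop("composition multiplicities must be > 0")
  structure(list(ids = ids, mults = mults), class = "composition")
}

#' @export
length.composition <- function(x) length(x$ids)

#' @export
format.composition <- function(x, ...) {
  if (length(x) == 0L) return("<empty composition>")
  paste(paste0(format(x$mults), " x ", x$ids), collapse = " + ")
}

#' @export
print.composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Net cofactor ledger of a composition
#'
#' Resolves every term against the library (reactions first, then pathways;
#' pathway-in-pathway references are followed to depth 3 with cycle
#' detection) and returns the multiplicity-weighted sum of the constituent
#' reaction stoichiometries. The result is linear in the multiplicities and
#' exact: an empty composition gives the empty ledger.
#'
#' @param comp a \code{\link{composition}} (or a pathway id as a shorthand
#'   for that pathway's composition).
#' @param library an \code{axis_library}; defaults to the built-in one.
#' @return a \code{\link{ledger}}.
#' @export
net_ledger <- function(comp, library = axis_library()) {
  if (is.character(comp) && length(comp) == 1L)
    comp <- composition(comp, rat(1))
  stopifnot(inherits(comp, "composition"))
  .net_ledger_rec(comp, library, depth = 0L, stack = character())
}

.net_ledger_rec <- function(comp, library, depth, stack) {
  parts <- list()
  weights <- rat(numeric(0), numeric(0))
  for (i in seq_len(length(comp))) {
    id <- comp$ids[i]
    m <- comp$mults[i]
    if (!is.null(library$reactions[[id]])) {
      parts[[length(parts) + 1L]] <- library$reactions[[id]]$ledger
      weights <- c(weights, m)
    } else if (!is.null(library$pathways[[id]])) {
      if (id %in% stack)
        stop("cyclic pathway definition: ", paste(c(stack, id), collapse = " -> "))
      if (depth >= 3L)
        stop("pathway nesting deeper than 3 at '", id, "'")
      sub <- .net_ledger_rec(library$pathways[[id]]$composition, library,
                             depth + 1L, c(stack, id))
      parts[[length(parts) + 1L]] <- sub
      weights <- c(weights, m)
    } else {
      stop("unknown reaction or pathway id: '", id, "'")
    }
  }
  if (!length(parts)) return(ledger())
  combine_ledgers(parts, weights)
}
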