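#' Cofactor ledgers
#'
#' A ledger is the net, signed, exact-rational stoichiometry of a reaction or
#' a weighted composition of reactions over the package's metabolic species
#' universe: negative entries are consumed, positive entries are produced,
#' and zero entries are dropped. Ledgers are the bookkeeping substrate for
#' all ATP-yield and redox-closure calculations.
#'
#' @param species character vector of species ids (e.g. \code{"ATP"},
#'   \code{"NADPH"}, \code{"FADH2"}).
#' @param amounts a \code{\link{rat}} vector (or anything coercible) of the
#'   same length.
#' @return an object of class \code{"cofactor_ledger"}.
#' @seealso \code{\link{net_ledger}}, \code{\link{combine_ledgers}},
#'   \code{\link{pair_closure_residuals}}, \code{\link{electron_yield}}
#' @export
ledger <- function(species = character(), amounts = rat(numeric(0), numeric(0))) {
  amounts <- rat(amounts)
  stopifnot(is.character(species), length(species) == length(amounts))
  if (anyDuplicated(species)) stop("duplicate species in ledger: ",
                                   paste(unique(species[duplicated(species)]), collapse = ", "))
  keep <- !rat_is_zero(amounts)
  structure(list(species = species[keep], amount = amounts[keep]),
            class = "cofactor_ledger")
}

#' @export
length.cofactor_ledger <- function(x) length(x$species)

#' Net amount of one species in a ledger
#'
#' @param x a \code{cofactor_ledger}.
#' @param species a single species id.
#' @return a length-1 \code{rat}; exact zero if the species is absent.
#' @export
ledger_entry <- function(x, species) {
  stopifnot(inherits(x, "cofactor_ledger"), length(species) == 1L)
  i <- match(species, x$species)
  if (is.na(i)) rat(0) else x$amount[i]
}

#' @export
as.data.frame.cofactor_ledger <- function(x, ...) {
  data.frame(species = x$species,
             net = as.character(x$amount),
             net_numeric = as.numeric(x$amount),
             stringsAsFactors = FALSE)
}

#' @export
format.cofactor_ledger <- function(x, ...) {
  if (length(x) == 0L) return("<empty ledger>")
  paste0(x$species, ": ", format(x$amount), collapse = ", ")
}

#' @export
print.cofactor_ledger <- function(x, ...) {
  cat("Cofactor ledger (", length(x), " species)\n", sep = "")
  if (length(x)) {
    df <- as.data.frame(x)
    print(df[, c("species", "net")], row.names = FALSE)
  }
  invisible(x)
}

#' Entrywise weighted sum of ledgers
#'
#' Linear combination of ledgers with signed exact-rational weights; zero
#' entries are dropped from the result. \code{combine_ledgers(list(L), list(-1))}
#' negates a ledger, and combining a ledger with its negation gives the empty
#' ledger exactly.
#'
#' @param ledgers list of \code{cofactor_ledger} objects.
#' @param weights list (or \code{rat} vector) of signed exact rationals, one
#'   per ledger.
#' @return a \code{cofactor_ledger}.
#' @export
combine_ledgers <- function(ledgers, weights) {
  if (inherits(ledgers, "cofactor_ledger")) ledgers <- list(ledgers)
  if (!is.list(weights) && !inherits(weights, "rat")) weights <- as.list(weights)
  nw <- if (inherits(weights, "rat")) length(weights) else length(weights)
  if (length(ledgers) != nw)
    stop("combine_ledgers: ", length(ledgers), " ledgers but ", nw, " weights")
  acc_sp <- character()
  acc_amt <- rat(numeric(0), numeric(0))
  for (i in seq_along(ledgers)) {
    l <- ledgers[[i]]
    stopifnot(inherits(l, "cofactor_ledger"))
    w <- if (inherits(weights, "rat")) weights[i] else rat(weights[[i]])
    for (j in seq_len(length(l))) {
      sp <- l$species[j]
      k <- match(sp, acc_sp)
      v <- w * l$amount[j]
      if (is.na(k)) {
        acc_sp <- c(acc_sp, sp)
        acc_amt <- c(acc_amt, v)
      } else {
        acc_amt[k] <- acc_amt[k] + v
      }
    }
  }
  ledger(acc_sp, acc_amt)
}

#' Conjugate-pair closure residuals
#'
#' For every conjugate cofactor pair in the species universe (ATP/ADP,
#' NAD+/NADH, NADP/NADPH, FAD/FADH2, GTP/GDP) the residual is
#' \code{net(oxidized) + net(reduced)}. An all-zero result means the ledger
#' only interconverts the members of each pair, which holds by construction
#' for every shipped reaction and hence every composition of them. Species
#' without a conjugate partner are skipped.
#'
#' @param x a \code{cofactor_ledger}.
#' @param library an axis library (defaults to the shipped one) providing the
#'   species universe.
#' @return data.frame with columns \code{pair}, \code{residual} (exact,
#'   character) and \code{residual_numeric}.
#' @export
pair_closure_residuals <- function(x, library = axis_library()) {
  stopifnot(inherits(x, "cofactor_ledger"))
  sp <- library$species
  red <- sp$id[!is.na(sp$conjugate_of) & sp$electrons_carried >= 0 & !is.na(sp$conjugate_of)]
  # enumerate each unordered pair once, keyed by the reduced/second member
  seen <- character()
  pairs <- list()
  for (id in sp$id) {
    mate <- sp$conjugate_of[match(id, sp$id)]
    if (is.na(mate)) next
    key <- paste(sort(c(id, mate)), collapse = "/")
    if (key %in% seen) next
    seen <- c(seen, key)
    pairs[[key]] <- c(id, mate)
  }
  res <- rat(numeric(0), numeric(0))
  for (p in pairs) res <- c(res, ledger_entry(x, p[1]) + ledger_entry(x, p[2]))
  data.frame(pair = names(pairs),
             residual = as.character(res),
             residual_numeric = as.numeric(res),
             stringsAsFactors = FALSE)
}

#' Electrons delivered onto reduced carriers
#'
#' Sums \code{net x electrons_carried} over reduced cofactor species with a
#' positive net. Complete oxidation of one glucose delivers 24 electrons
#' whichever route is taken: 10 NADH + 2 FADH2 via glycolysis and the citric
#' acid cycle, or 12 FADH2 via the NADPH-FADH2 axis.
#'
#' @inheritParams pair_closure_residuals
#' @return a length-1 \code{rat}.
#' @export
electron_yield <- function(x, library = axis_library()) {
  stopifnot(inherits(x, "cofactor_ledger"))
  sp <- library$species
  total <- rat(0)
  for (j in seq_len(length(x))) {
    e <- sp$electrons_carried[match(x$species[j], sp$id)]
    if (is.na(e) || e == 0) next
    if (x$amount[j] > rat(0)) total <- total + x$amount[j] * rat(e)
  }
  total
}

#' Write a ledger to TSV or JSON
#'
#' @param x a \code{cofactor_ledger}.
#' @param path output file path; format chosen by extension (\code{.tsv} or
#'   \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_ledger <- function(x, path) {
  stopifnot(inherits(x, "cofactor_ledger"))
  df <- as.data.frame(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(species = df$species, net = df$net, net_numeric = df$net_numeric),
      path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.table(df[, c("species", "net")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV ledger written by \code{\link{write_ledger}}
#' @param path file path.
#' @return a \code{cofactor_ledger}.
#' @export
read_ledger <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ledger(df$species, rat(as.character(df$net)))
}
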