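# Pathway-level access: named pathway definitions in the paper's idealized
# per-acetyl-CoA mode and an exact palmitate (C16) mode, plus the curated
# gene sets transcribed from the reanalyzed expression tables.

# pathway ids that have a distinct exact-C16 definition
.exact_c16_map <- c(fa_cycling = "fa_cycling_c16",
                    fa_synthesis = "fa_synthesis_c16",
                    beta_oxidation = "beta_oxidation_c16")

#' Retrieve a pathway definition
#'
#' @param id pathway id: one of \code{ppp}, \code{fa_synthesis},
#'   \code{carnitine_shuttle}, \code{beta_oxidation}, \code{citrate_shuttle},
#'   \code{fa_cycling}, \code{glycolysis_tca}, \code{ketogenesis},
#'   \code{ketolysis}, \code{lactate_shuttle}.
#' @param mode \code{"idealized"} (the per-acetyl-CoA bookkeeping used for
#'   the headline yields) or \code{"exact_c16"} (chain-length-exact palmitate
#'   accounting: 7 malonyl-CoA activations because the primer acetyl-CoA is
#'   used directly, 7 beta-oxidation rounds, 8 citrate-shuttle exports).
#'   \code{exact_c16} exists for \code{fa_cycling}, \code{fa_synthesis} and
#'   \code{beta_oxidation} only.
#' @param acsl_activation if \code{TRUE}, charge an optional 2-ATP-equivalent
#'   acyl-CoA re-activation per C16 cycle (sensitivity analysis; the default
#'   follows the definition in which cycling starts and ends at
#'   palmitoyl-CoA, so no re-activation cost is due).
#' @param library an \code{axis_library}.
#' @return a list with \code{id}, \code{name}, \code{mode}, \code{unit},
#'   \code{composition} and the resolved net \code{ledger}.
#' @export
get_pathway <- function(id, mode = c("idealized", "exact_c16"),
                        acsl_activation = FALSE, library = axis_library()) {
  mode <- match.arg(mode)
  key <- id
  if (mode == "exact_c16") {
    if (!id %in% names(.exact_c16_map))
      stop("pathway '", id, "' has no exact_c16 mode")
    key <- .exact_c16_map[[id]]
  }
  p <- library$pathways[[key]]
  if (is.null(p)) stop("unknown pathway id: '", id, "'")
  comp <- p$composition
  if (acsl_activation) {
    if (mode != "exact_c16" || id != "fa_cycling")
      stop("acsl_activation applies to fa_cycling in exact_c16 mode only")
    comp <- composition(c(comp$ids, "r_acsl_activation"), c(comp$mults, rat(1)))
  }
  out <- list(id = id, name = p$name, mode = mode, unit = p$unit,
              composition = comp,
              ledger = net_ledger(comp, library))
  class(out) <- "pathway_def"
  out
}

#' @export
print.pathway_def <- function(x, ...) {
  cat("Pathway '", x$id, "' (", x$mode, ", ", x$unit, ")\n", sep = "")
  cat("  ", format(x$composition), "\n", sep = "")
  cat("  net: ", format(x$ledger), "\n", sep = "")
  invisible(x)
}

#' Citrate shuttle exchange-substrate variants
#'
#' The mitochondrial citrate transporter accepts different polyanions as
#' exchange substrates. The \code{malate} variant (malate export recycled via
#' malate dehydrogenase and malic enzyme) is the default shuttle used in all
#' headline ledgers: \{ATP: -2, NADH: -1, NADPH: +1\} per acetyl-CoA. The
#' \code{PEP} variant exchanges citrate against phosphoenolpyruvate, which
#' avoids the co-import of reducing equivalents into the mitochondrion; its
#' declared ledger is \{ATP: -1, GTP: -1\} per acetyl-CoA with NADH net zero.
#'
#' @param exchange_substrate \code{"malate"} or \code{"PEP"}.
#' @param library an \code{axis_library}.
#' @return a \code{pathway_def}.
#' @export
citrate_shuttle_variant <- function(exchange_substrate = c("malate", "PEP"),
                                    library = axis_library()) {
  exchange_substrate <- match.arg(exchange_substrate)
  rid <- if (exchange_substrate == "malate") "r_cshuttle_malate" else "r_cshuttle_pep"
  comp <- composition(rid, rat(1))
  out <- list(id = paste0("citrate_shuttle_", tolower(exchange_substrate)),
              name = library$reactions[[rid]]$name,
              mode = "idealized", unit = "per_acetyl_coa",
              composition = comp, ledger = net_ledger(comp, library))
  class(out) <- "pathway_def"
  out
}

#' Fatty-acid cycling ledger for an arbitrary even chain length
#'
#' Generalizes the exact palmitate accounting to a C(2m) chain: m - 1
#' malonyl-CoA activations, 2(m - 1) FASN reductions, m - 1 beta-oxidation
#' rounds and m citrate-shuttle exports. As the chain grows, the
#' per-acetyl-CoA cost converges to the idealized values (-3 ATP, -1 NADPH,
#' +1 FADH2 per acetyl-CoA).
#'
#' @param n_carbons even chain length >= 4.
#' @param library an \code{axis_library}.
#' @return a \code{\link{ledger}} for one full cycle of the C(n) chain
#'   (m = n_carbons/2 acetyl-CoA units).
#' @export
fa_cycling_cn_ledger <- function(n_carbons, library = axis_library()) {
  stopifnot(length(n_carbons) == 1L, n_carbons >= 4, n_carbons %% 2 == 0)
  m <- n_carbons / 2
  synth <- ledger(c("AcCoA", "ATP", "ADP", "NADPH", "NADP"),
                  rat(c(-m, -(m - 1), m - 1, -2 * (m - 1), 2 * (m - 1))))
  boxid <- ledger(c("NAD+", "NADH", "FAD", "FADH2", "AcCoA"),
                  rat(c(-(m - 1), m - 1, -(m - 1), m - 1, m)))
  shuttle <- library$reactions[["r_cshuttle_malate"]]$ledger
  combine_ledgers(list(synth, boxid, shuttle), list(1, 1, m))
}

#' Curated pathway gene sets
#'
#' Returns the gene symbols assigned to a pathway in one of the transcribed
#' source tables, in the printed order. Sources: \code{table2} (MPP-treated
#' LUHMES RNA-seq), \code{table4_liver} / \code{table4_adipose} /
#' \code{table4_muscle} (methionine-restricted rat microarray),
#' \code{table6} (metformin-treated HepG2 RNA-seq) and
#' \code{table3_regulators} (regulatory genes of fatty acid metabolism).
#'
#' @param pathway_id pathway key within the source, e.g.
#'   \code{"pentose_phosphate"}, \code{"citrate_shuttle"},
#'   \code{"regulators"}.
#' @param source source table id.
#' @return character vector of gene symbols (possibly empty).
#' @export
gene_set <- function(pathway_id,
                     source = c("table2", "table4_liver", "table4_adipose",
                                "table4_muscle", "table6", "table3_regulators")) {
  source <- match.arg(source)
  sets <- load_gene_sets()[[source]]
  if (!pathway_id %in% names(sets))
    stop("unknown pathway '", pathway_id, "' for source '", source, "'")
  unlist(sets[[pathway_id]]) %||% character(0)
}

#' Load all curated gene sets
#'
#' @param path optional alternative JSON file; defaults to the shipped
#'   transcription.
#' @return nested list: source table -> pathway -> character vector.
#' @export
load_gene_sets <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.nadphaxis_env$gene_sets)) {
      f <- system.file("extdata", "gene_sets.json", package = "nadphaxis")
      .nadphaxis_env$gene_sets <- jsonlite::read_json(f, simplifyVector = TRUE)
    }
    return(.nadphaxis_env$gene_sets)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Gene symbols printed under more than one pathway of a source table
#'
#' The source tables mostly assign each gene to a single pathway, but a few
#' junction enzymes are printed under two headings (e.g. citrate synthase and
#' mitochondrial malate dehydrogenase under both the citric acid cycle and
#' the citrate shuttle). This reports every such overlap so the shipped sets
#' can be audited.
#'
#' @param source source table id as in \code{\link{gene_set}}.
#' @return data.frame with columns \code{gene}, \code{pathways}
#'   (comma-separated), one row per multiply-assigned symbol.
#' @export
gene_set_overlaps <- function(source = "table2") {
  sets <- load_gene_sets()[[source]]
  if (is.null(sets)) stop("unknown source table: '", source, "'")
  all_genes <- unlist(lapply(names(sets), function(p)
    stats::setNames(rep(p, length(sets[[p]])), unlist(sets[[p]]))))
  dup <- unique(names(all_genes)[duplicated(names(all_genes))])
  if (!length(dup))
    return(data.frame(gene = character(), pathways = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    gene = dup,
    pathways = vapply(dup, function(g)
      paste(unname(all_genes[names(all_genes) == g]), collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
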