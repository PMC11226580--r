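# Readers and writers: DE result tables (TSV), metabolite tables, screen
# reports. TSV, UTF-8, Unix newlines throughout.

#' Read a differential-expression result table
#'
#' Expects a TSV with header columns \code{gene}, \code{fold_change},
#' \code{p_value}, optionally \code{baseline_rpkm} (required downstream for
#' the RNA-seq platform) and \code{tissue}. Extra columns are carried along.
#' Rows are validated with their file row numbers in error messages.
#'
#' @param path TSV file path.
#' @return data.frame of typed records with attribute \code{"path"}.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "fold_change", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  rowno <- seq_len(nrow(df)) + 1L  # header is line 1
  for (col in intersect(c("fold_change", "p_value", "baseline_rpkm"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("non-numeric ", col, " in ", path, " at row(s) ",
           paste(rowno[bad], collapse = ", "))
    df[[col]] <- v
  }
  bad_fc <- which(is.na(df$fold_change) | df$fold_change <= 0)
  if (length(bad_fc))
    stop("fold_change must be a positive ratio; offending row(s) in ", path,
         ": ", paste(rowno[bad_fc], collapse = ", "))
  bad_p <- which(is.na(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad_p))
    stop("p_value must lie in [0, 1]; offending row(s) in ", path, ": ",
         paste(rowno[bad_p], collapse = ", "))
  attr(df, "path") <- path
  df
}

#' Write a DE table (round-trips with \code{\link{read_de_table}})
#'
#' @param records data.frame of DE records.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a metabolite fold-change table
#'
#' TSV with columns \code{metabolite}, \code{tissue}, \code{fold_change},
#' \code{significant}.
#'
#' @param path TSV file path; defaults to the shipped transcription of the
#'   methionine-restriction metabolite panel.
#' @return data.frame.
#' @export
read_metabolite_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table5_metabolites.tsv",
                                package = "nadphaxis")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Shipped expression-table fixtures
#'
#' Loads one of the transcribed source tables:
#' \code{table2} (MPP-treated LUHMES RNA-seq), \code{table4} (methionine-
#' restricted rat microarray, all tissues), \code{table6} (metformin-treated
#' HepG2 RNA-seq), \code{table3} (regulatory genes), \code{table5}
#' (metabolites).
#'
#' @param which fixture id.
#' @return data.frame.
#' @export
axis_fixture <- function(which = c("table2", "table4", "table6", "table3",
                                   "table5")) {
  which <- match.arg(which)
  f <- switch(which,
    table2 = "table2_mpp_luhmes.tsv",
    table4 = "table4_metr_rats.tsv",
    table6 = "table6_metformin_hepg2.tsv",
    table3 = "table3_regulators.tsv",
    table5 = "table5_metabolites.tsv")
  utils::read.delim(system.file("extdata", f, package = "nadphaxis"),
                    stringsAsFactors = FALSE)
}

#' Write a screen report directory
#'
#' One TSV per pathway (named \code{<pathway>.tsv}), a \code{summary.tsv}
#' over all pathways, and a \code{manifest.json} recording the screen
#' configuration, the seed and the package version. Output is byte-stable:
#' rewriting the same inputs produces identical files.
#'
#' @param screen a \code{\link{screen_pathways}} result.
#' @param path output directory (created if absent).
#' @param seed optional seed to record in the manifest.
#' @return the directory path, invisibly.
#' @export
write_report <- function(screen, path, seed = NULL) {
  stopifnot(inherits(screen, "pathway_screen"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (file.access(path, 2) != 0) stop("output directory not writable: ", path)
  for (pw in names(screen))
    utils::write.table(screen[[pw]], file.path(path, paste0(pw, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(screen_summary(screen), file.path(path, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(screen, "config")
  manifest <- list(package = "nadphaxis",
                   version = as.character(utils::packageVersion("nadphaxis")),
                   config = unclass(cfg),
                   seed = seed,
                   pathways = names(screen))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
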