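# Curated gene-set screening of differential-expression result tables under
# the platform-specific thresholds used for the reanalyzed datasets:
# RNA-seq: p at or below 1e-6 (n = 3) among genes with baseline >= 1 RPKM;
# microarray: p at or below 0.05 (n = 6) and fold change > 3/2 or < 2/3.
# The p comparison is inclusive because published tables round p to one
# significant figure, so a printed value exactly at the threshold denotes a
# significant call.

#' Screening configuration
#'
#' @param platform \code{"rnaseq"} or \code{"microarray"}.
#' @param p_threshold significance threshold; default 1e-6 for RNA-seq and
#'   0.05 for microarray.
#' @param fc_up_threshold,fc_down_threshold fold-change thresholds, applied
#'   on the microarray platform only. The defaults are exactly 3/2 and 2/3;
#'   the down threshold is kept as the rational 2/3 (compared as
#'   \code{3 * FC < 2}) to avoid decimal drift.
#' @param expression_floor RPKM floor for the RNA-seq platform; genes with a
#'   baseline below it are reported as \code{low_expression}, never as
#'   significant.
#' @param replicates_n replicates per arm (metadata; 3 for the RNA-seq
#'   datasets, 6 for the microarray).
#' @return an object of class \code{"screen_config"}.
#' @export
screen_config <- function(platform = c("rnaseq", "microarray"),
                          p_threshold = NULL,
                          fc_up_threshold = 3 / 2,
                          fc_down_threshold = 2 / 3,
                          expression_floor = 1,
                          replicates_n = NULL) {
  platform <- match.arg(platform)
  if (is.null(p_threshold))
    p_threshold <- if (platform == "rnaseq") 1e-6 else 0.05
  if (is.null(replicates_n))
    replicates_n <- if (platform == "rnaseq") 3L else 6L
  stopifnot(p_threshold > 0, fc_up_threshold > 1, fc_down_threshold < 1,
            expression_floor > 0)
  structure(list(platform = platform, p_threshold = p_threshold,
                 fc_up_threshold = fc_up_threshold,
                 fc_down_threshold = fc_down_threshold,
                 expression_floor = expression_floor,
                 replicates_n = as.integer(replicates_n)),
            class = "screen_config")
}

.gene_classes <- c("significant_up", "significant_down",
                   "not_significant", "low_expression")

#' Classify differential-expression records
#'
#' RNA-seq: \code{low_expression} if the baseline is below the expression
#' floor (the source tables bracket such entries as warranting cautious
#' interpretation); otherwise \code{significant_up}/\code{significant_down}
#' if p is below the threshold and the fold change is above/below 1;
#' otherwise \code{not_significant}. Microarray: significant only if p is
#' below the threshold AND the fold change clears 3/2 (up) or 2/3 (down).
#'
#' @param fold_change positive treated/control ratio (vectorized).
#' @param p_value p value in [0, 1] (vectorized).
#' @param baseline baseline expression in RPKM; required for the RNA-seq
#'   platform, ignored for microarray.
#' @param config a \code{\link{screen_config}}.
#' @return character vector of classes.
#' @export
classify_gene <- function(fold_change, p_value, baseline = NULL,
                          config = screen_config("rnaseq")) {
  stopifnot(inherits(config, "screen_config"))
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop("fold_change must be positive")
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1))
    stop("p_value must lie in [0, 1]")
  n <- length(fold_change)
  stopifnot(length(p_value) == n)
  if (config$platform == "rnaseq") {
    if (is.null(baseline) || any(is.na(baseline)))
      stop("the rnaseq platform requires a baseline (RPKM) for every record")
    stopifnot(length(baseline) == n)
    cls <- rep("not_significant", n)
    sig <- p_value <= config$p_threshold
    cls[sig & fold_change > 1] <- "significant_up"
    cls[sig & fold_change < 1] <- "significant_down"
    cls[baseline < config$expression_floor] <- "low_expression"
    cls
  } else {
    cls <- rep("not_significant", n)
    sig <- p_value <= config$p_threshold
    up <- fold_change > config$fc_up_threshold
    # default down threshold is the exact rational 2/3: compare 3 FC < 2
    down <- if (config$fc_down_threshold == 2 / 3) 3 * fold_change < 2
            else fold_change < config$fc_down_threshold
    cls[sig & up] <- "significant_up"
    cls[sig & down] <- "significant_down"
    cls
  }
}

#' Screen curated pathways in a DE table
#'
#' Builds one table per pathway, restricted to the pathway's curated gene
#' set, rows in gene-set order. Genes of the set absent from the records are
#' reported with class \code{missing}, never silently dropped. Gene symbols
#' are matched case-insensitively but reported as stored in the gene set.
#'
#' @param records data.frame as returned by \code{\link{read_de_table}}:
#'   columns \code{gene}, \code{fold_change}, \code{p_value}, optionally
#'   \code{baseline_rpkm} and \code{tissue}.
#' @param gene_sets named list pathway -> character vector (one source table
#'   of \code{\link{load_gene_sets}}).
#' @param config a \code{\link{screen_config}}.
#' @param tissue optional tissue to filter multi-tissue records by before
#'   screening.
#' @return a named list of class \code{"pathway_screen"}; each element is a
#'   data.frame with columns \code{gene}, \code{fold_change}, \code{p_value},
#'   \code{baseline_rpkm}, \code{class}.
#' @export
screen_pathways <- function(records, gene_sets, config, tissue = NULL) {
  stopifnot(is.data.frame(records), inherits(config, "screen_config"))
  if (!length(gene_sets)) stop("gene_sets must be non-empty")
  if (!is.null(tissue)) {
    if (is.null(records$tissue))
      stop("tissue filter requested but records have no tissue column")
    records <- records[records$tissue == tissue, , drop = FALSE]
  }
  key <- if (!is.null(records$tissue) && is.null(tissue))
    paste(toupper(records$gene), records$tissue) else toupper(records$gene)
  if (anyDuplicated(key)) {
    dup <- unique(records$gene[duplicated(key)])
    stop("duplicate records for: ", paste(dup, collapse = ", "))
  }
  if (is.null(records$baseline_rpkm)) records$baseline_rpkm <- NA_real_

  out <- list()
  for (pw in names(gene_sets)) {
    genes <- unlist(gene_sets[[pw]])
    if (is.null(genes) || !length(genes)) {
      out[[pw]] <- data.frame(gene = character(), fold_change = numeric(),
                              p_value = numeric(), baseline_rpkm = numeric(),
                              class = character(), stringsAsFactors = FALSE)
      next
    }
    i <- match(toupper(genes), toupper(records$gene))
    tab <- data.frame(gene = genes,
                      fold_change = records$fold_change[i],
                      p_value = records$p_value[i],
                      baseline_rpkm = records$baseline_rpkm[i],
                      class = NA_character_,
                      stringsAsFactors = FALSE)
    found <- !is.na(i)
    if (any(found))
      tab$class[found] <- classify_gene(tab$fold_change[found],
                                        tab$p_value[found],
                                        if (config$platform == "rnaseq")
                                          tab$baseline_rpkm[found],
                                        config)
    tab$class[!found] <- "missing"
    out[[pw]] <- tab
  }
  structure(out, class = c("pathway_screen", "list"), config = config)
}

#' Summary counts for one screened pathway table
#'
#' @param table one element of a \code{\link{screen_pathways}} result.
#' @return named list: \code{n_in_set}, \code{n_detected}, \code{n_up},
#'   \code{n_down}, \code{n_low}, \code{n_missing}.
#' @export
pathway_summary <- function(table) {
  stopifnot(is.data.frame(table), "class" %in% names(table))
  list(n_in_set = nrow(table),
       n_detected = sum(table$class != "missing"),
       n_up = sum(table$class == "significant_up"),
       n_down = sum(table$class == "significant_down"),
       n_low = sum(table$class == "low_expression"),
       n_missing = sum(table$class == "missing"))
}

#' Summary data.frame over all screened pathways
#'
#' @param screen a \code{\link{screen_pathways}} result.
#' @return data.frame with one row per pathway.
#' @export
screen_summary <- function(screen) {
  rows <- lapply(names(screen), function(pw) {
    s <- pathway_summary(screen[[pw]])
    cbind(data.frame(pathway = pw, stringsAsFactors = FALSE),
          as.data.frame(s))
  })
  do.call(rbind, rows)
}

#' Lactate/pyruvate fold-change ratio
#'
#' A cytosolic NADH/NAD+ redox proxy: the ratio of the lactate fold change
#' to the pyruvate fold change in one tissue. Reported to two decimals
#' (half-even) alongside full precision, matching the printed table cells.
#'
#' @param metabolites data.frame with columns \code{metabolite},
#'   \code{tissue}, \code{fold_change} (as read by
#'   \code{\link{read_metabolite_table}}).
#' @param tissue tissue column to use.
#' @param lactate,pyruvate metabolite names to look up.
#' @return list with \code{ratio} (full precision) and \code{rounded} (two
#'   decimals).
#' @export
lp_ratio <- function(metabolites, tissue,
                     lactate = "Lactate", pyruvate = "Pyruvate") {
  pick <- function(name) {
    i <- which(metabolites$metabolite == name & metabolites$tissue == tissue)
    if (!length(i)) return(NA_real_)
    metabolites$fold_change[i[1]]
  }
  l <- pick(lactate)
  p <- pick(pyruvate)
  if (is.na(l) || is.na(p) || p == 0)
    stop("L/P ratio undefined for tissue '", tissue,
         "': lactate or pyruvate fold change absent")
  r <- l / p
  list(ratio = r, rounded = round(r, 2))
}
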