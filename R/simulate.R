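# Scenario-driven simulation of differential-expression result tables with
# the statistical structure the screen assumes: pathway-coherent true fold
# changes, log-normal replicate noise and two-sample p-values, plus a truth
# table for recovery scoring. Stands in for the external datasets so every
# screening operation is testable offline.

.sim_scenarios <- c("mpp_like", "metformin_like", "metr_liver",
                    "metr_adipose", "null")

# per-scenario mean true log2 fold change for curated pathway members;
# magnitudes follow the 1.5- to 8-fold range of the printed source tables
.scenario_effects <- list(
  mpp_like = list(source = "table2", platform = "rnaseq", effects = c(
    glycolysis = 1.5, citric_acid_cycle = 1.0, pentose_phosphate = 1.5,
    citrate_shuttle = 1.2, fatty_acid_synthesis = 1.0,
    fatty_acid_oxidation = 0.8)),
  metformin_like = list(source = "table6", platform = "rnaseq", effects = c(
    glycolysis = -0.7, citric_acid_cycle = 0.5, pentose_phosphate = 0.5,
    citrate_shuttle = 0.5, fatty_acid_synthesis = 0.9,
    carnitine_shuttle = -1.2, fatty_acid_oxidation = -0.6)),
  metr_liver = list(source = "table4_liver", platform = "microarray", effects = c(
    glycolysis = -0.8, pentose_phosphate = 0.8, citrate_shuttle = -1.0,
    fatty_acid_synthesis = -1.5, fatty_acid_oxidation = 0.8)),
  metr_adipose = list(source = "table4_adipose", platform = "microarray", effects = c(
    glycolysis = 0.8, citric_acid_cycle = 0.7, citrate_shuttle = 0.8,
    fatty_acid_synthesis = 1.5, fatty_acid_oxidation = 0.6)),
  null = list(source = "table2", platform = "rnaseq", effects = numeric(0)))

#' Simulation configuration
#'
#' @param scenario one of \code{mpp_like}, \code{metformin_like},
#'   \code{metr_liver}, \code{metr_adipose}, \code{null}. Scenarios fix the
#'   platform, the curated gene-set source and the direction pattern of the
#'   per-pathway effects (the methionine-restriction liver and adipose
#'   scenarios regulate SCD/ACLY/ACACA in opposite directions, mirroring the
#'   reciprocal in vivo pattern).
#' @param n_genes total genes simulated (default 11000, the scale of the
#'   reanalyzed RNA-seq experiments); must cover the curated sets.
#' @param replicates replicates per arm (default 3, as in the RNA-seq
#'   designs; the microarray study used 6).
#' @param effect_sd sd of the true log2 fold change around the pathway mean.
#' @param background_sd sd of true log2 fold changes of genes outside the
#'   curated sets (0 in the null scenario: all true effects are exactly 0).
#' @param noise_sd replicate-level log2 measurement noise.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline RPKM distribution (defaults give roughly 10 percent of genes
#'   below 1 RPKM).
#' @param effects optional named vector overriding the scenario's
#'   per-pathway mean log2 fold changes.
#' @param p_method \code{"welch"} (Welch two-sample t across replicates) or
#'   \code{"z"} (known-variance z test, emulating the large-df Wald
#'   statistics of upstream count pipelines, which at n = 3 can reach far
#'   smaller p values than a t test can).
#' @param seed integer; fixes the full output.
#' @return an object of class \code{"sim_config"}.
#' @export
simulation_config <- function(scenario = c("mpp_like", "metformin_like",
                                           "metr_liver", "metr_adipose", "null"),
                              n_genes = 11000L, replicates = 3L,
                              effect_sd = 0.2, background_sd = 0.15,
                              noise_sd = 0.2,
                              baseline_meanlog = log(8), baseline_sdlog = 1.6,
                              effects = NULL,
                              p_method = c("welch", "z"),
                              seed = 1L) {
  scenario <- match.arg(scenario)
  p_method <- match.arg(p_method)
  preset <- .scenario_effects[[scenario]]
  eff <- effects %||% preset$effects
  if (scenario == "null") {
    eff <- numeric(0)
    background_sd <- 0
  }
  sets <- load_gene_sets()[[preset$source]]
  if (length(eff) && !all(names(eff) %in% names(sets)))
    stop("effect map names pathways absent from the '", preset$source,
         "' gene sets: ",
         paste(setdiff(names(eff), names(sets)), collapse = ", "))
  n_curated <- length(unique(unlist(sets)))
  if (n_genes < n_curated)
    stop("n_genes (", n_genes, ") smaller than the curated set size (",
         n_curated, ")")
  stopifnot(replicates >= 2, effect_sd > 0, background_sd >= 0, noise_sd > 0)
  structure(list(scenario = scenario, platform = preset$platform,
                 source = preset$source, n_genes = as.integer(n_genes),
                 replicates = as.integer(replicates),
                 effects = eff, effect_sd = effect_sd,
                 background_sd = background_sd, noise_sd = noise_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 p_method = p_method, seed = as.integer(seed)),
            class = "sim_config")
}

# vectorized Welch two-sample t-test on log2 expression matrices
.welch_p <- function(xt, xc) {
  n1 <- ncol(xt); n2 <- ncol(xc)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- apply(xt, 1, stats::var); v2 <- apply(xc, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

.z_p <- function(xt, xc, sd0) {
  z <- (rowMeans(xt) - rowMeans(xc)) /
    (sd0 * sqrt(1 / ncol(xt) + 1 / ncol(xc)))
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Simulate a differential-expression table with known truth
#'
#' For each gene: a baseline RPKM is drawn log-normally; the true log2 fold
#' change is drawn around the scenario's pathway mean (curated members) or
#' the background distribution (all other genes); replicate-level log2
#' expressions get independent Gaussian noise in both arms; the p-value
#' comes from a two-sample location test across replicates. Deterministic
#' under a fixed seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{records} (data.frame: gene, fold_change, p_value,
#'   baseline_rpkm for RNA-seq) and \code{truth} (data.frame: gene, pathway,
#'   true_log2fc, baseline_rpkm, intended_class).
#' @export
simulate_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  sets <- load_gene_sets()[[config$source]]
  curated <- unique(unlist(sets))
  pathway_of <- rep(NA_character_, length(curated))
  for (pw in names(sets)) {
    hit <- match(unlist(sets[[pw]]), curated)
    pathway_of[hit[is.na(pathway_of[hit])]] <- pw
  }
  n_fill <- config$n_genes - length(curated)
  genes <- c(curated, sprintf("SYN%05d", seq_len(n_fill)))
  pathway <- c(pathway_of, rep(NA_character_, n_fill))

  baseline <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                            config$baseline_sdlog)
  mu <- ifelse(!is.na(pathway) & pathway %in% names(config$effects),
               unname(config$effects[pathway]), 0)
  sd_true <- ifelse(!is.na(pathway) & pathway %in% names(config$effects),
                    config$effect_sd, config$background_sd)
  true_lfc <- if (config$scenario == "null") rep(0, config$n_genes)
              else stats::rnorm(config$n_genes, mu, sd_true)

  nrep <- config$replicates
  base_l2 <- log2(baseline)
  xc <- matrix(stats::rnorm(config$n_genes * nrep, base_l2, config$noise_sd),
               ncol = nrep)
  xt <- matrix(stats::rnorm(config$n_genes * nrep, base_l2 + true_lfc,
                            config$noise_sd), ncol = nrep)
  fc <- 2^(rowMeans(xt) - rowMeans(xc))
  p <- if (config$p_method == "welch") .welch_p(xt, xc)
       else .z_p(xt, xc, config$noise_sd)

  records <- data.frame(gene = genes, fold_change = fc, p_value = p,
                        stringsAsFactors = FALSE)
  if (config$platform == "rnaseq") records$baseline_rpkm <- baseline

  scfg <- screen_config(config$platform)
  intended <- .intended_class(true_lfc, baseline, scfg)
  truth <- data.frame(gene = genes, pathway = pathway,
                      true_log2fc = true_lfc, baseline_rpkm = baseline,
                      intended_class = intended, stringsAsFactors = FALSE)
  list(records = records, truth = truth, config = config)
}

# the class a record should receive if the test recovered the generating
# truth exactly (thresholds applied to the true fold change)
.intended_class <- function(true_lfc, baseline, scfg) {
  cls <- rep("not_significant", length(true_lfc))
  if (scfg$platform == "rnaseq") {
    cls[true_lfc > 0] <- "significant_up"
    cls[true_lfc < 0] <- "significant_down"
    cls[baseline < scfg$expression_floor] <- "low_expression"
  } else {
    fc <- 2^true_lfc
    cls[fc > scfg$fc_up_threshold] <- "significant_up"
    cls[3 * fc < 2] <- "significant_down"
  }
  cls
}

#' Score screen calls against simulation truth
#'
#' @param records the simulated DE table (or any table with \code{gene},
#'   \code{fold_change}, \code{p_value}, optionally \code{baseline_rpkm}).
#' @param truth the truth table from \code{\link{simulate_expression}}.
#' @param config a \code{\link{screen_config}} for classification.
#' @return list with \code{sensitivity} (intended significant genes called
#'   significant in the right direction), \code{specificity} (intended
#'   not-significant genes not called), \code{false_positive_rate}
#'   (1 - specificity) and the underlying counts.
#' @export
recovery_report <- function(records, truth, config) {
  stopifnot(is.data.frame(records), is.data.frame(truth),
            inherits(config, "screen_config"))
  i <- match(truth$gene, records$gene)
  if (any(is.na(i)))
    stop("truth table names genes absent from the records: ",
         paste(utils::head(truth$gene[is.na(i)], 5), collapse = ", "))
  called <- classify_gene(records$fold_change[i], records$p_value[i],
                          if (config$platform == "rnaseq") records$baseline_rpkm[i],
                          config)
  intended <- truth$intended_class
  eval_mask <- intended != "low_expression" & called != "low_expression"
  pos <- eval_mask & intended %in% c("significant_up", "significant_down")
  neg <- eval_mask & intended == "not_significant"
  tp <- sum(pos & called == intended)
  fp <- sum(neg & called %in% c("significant_up", "significant_down"))
  sens <- if (sum(pos)) tp / sum(pos) else NA_real_
  fpr <- if (sum(neg)) fp / sum(neg) else NA_real_
  list(sensitivity = sens,
       specificity = if (is.na(fpr)) NA_real_ else 1 - fpr,
       false_positive_rate = fpr,
       n_positive = sum(pos), n_negative = sum(neg),
       true_positives = tp, false_positives = fp)
}
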