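# Gene classification under platform thresholds, pathway screening of the
# transcribed fixtures, summaries, and metabolite ratios.

test_that("classify_gene applies the RNA-seq decision rule", {
  cfg <- screen_config("rnaseq")
  expect_equal(classify_gene(1.75, 9e-14, 56, cfg), "significant_up")
  expect_equal(classify_gene(0.40, 1e-18, 13, cfg), "significant_down")
  expect_equal(classify_gene(3.00, 1e-10, 0.8, cfg), "low_expression")
  expect_equal(classify_gene(1.75, 1e-3, 56, cfg), "not_significant")
  # printed p values are rounded to one significant figure, so the boundary
  # is inclusive
  expect_equal(classify_gene(1.29, 1e-6, 14, cfg), "significant_up")
  expect_error(classify_gene(1.5, 1e-8, NULL, cfg), "baseline")
  expect_error(classify_gene(-1, 0.5, 10, cfg), "positive")
  expect_error(classify_gene(1.5, 1.2, 10, cfg), "\\[0, 1\\]")
})

test_that("classify_gene applies the microarray fold-change gate", {
  cfg <- screen_config("microarray")
  expect_equal(classify_gene(0.07, 5e-6, config = cfg), "significant_down")
  expect_equal(classify_gene(1.45, 0.001, config = cfg), "not_significant")
  expect_equal(classify_gene(1.51, 0.04, config = cfg), "significant_up")
  expect_equal(classify_gene(0.70, 0.001, config = cfg), "not_significant")
  expect_equal(classify_gene(3.00, 0.2, config = cfg), "not_significant")
  # the down threshold is the exact rational 2/3
  expect_equal(classify_gene(2 / 3, 0.01, config = cfg), "not_significant")
  expect_equal(classify_gene(0.66, 0.01, config = cfg), "significant_down")
})

test_that("threshold relaxation never removes a significant call", {
  set.seed(7)
  fc <- exp(stats::rnorm(300, 0, 0.7))
  p <- stats::runif(300)^3
  base <- stats::rlnorm(300, 2, 1.5)
  strict <- classify_gene(fc, p, base, screen_config("rnaseq", p_threshold = 1e-6))
  lax <- classify_gene(fc, p, base, screen_config("rnaseq", p_threshold = 1e-3))
  sig <- strict %in% c("significant_up", "significant_down")
  expect_true(all(strict[sig] == lax[sig]))
  strict_m <- classify_gene(fc, p, config = screen_config("microarray"))
  lax_m <- classify_gene(fc, p, config = screen_config(
    "microarray", p_threshold = 0.2, fc_up_threshold = 1.2,
    fc_down_threshold = 1 / 1.2))
  sig_m <- strict_m %in% c("significant_up", "significant_down")
  expect_true(all(strict_m[sig_m] == lax_m[sig_m]))
})

test_that("screen_pathways keeps gene-set order and reports missing genes", {
  records <- axis_fixture("table2")
  sets <- load_gene_sets()[["table2"]]
  scr <- screen_pathways(records, sets, screen_config("rnaseq"))
  expect_named(scr, names(sets))
  expect_equal(scr$pentose_phosphate$gene, c("G6PD", "PGLS", "PGD", "TKT"))
  # an empty record list flags every gene as missing rather than dropping it
  empty <- records[0, ]
  scr0 <- screen_pathways(empty, sets, screen_config("rnaseq"))
  expect_true(all(scr0$glycolysis$class == "missing"))
  expect_equal(pathway_summary(scr0$glycolysis)$n_missing, 14)
  # duplicated records are an input error naming the offender
  dup <- rbind(records, records[1, ])
  expect_error(screen_pathways(dup, sets, screen_config("rnaseq")), records$gene[1])
})

test_that("pathway summaries count the fixture classes as printed", {
  scr <- screen_pathways(axis_fixture("table2"), load_gene_sets()[["table2"]],
                         screen_config("rnaseq"))
  fao <- pathway_summary(scr$fatty_acid_oxidation)
  expect_equal(fao$n_in_set, 6)
  expect_equal(fao$n_up, 4)   # ACADVL, HADH, HADHA, HADHB
  expect_equal(fao$n_down, 2) # ACADM, ACAD9
  up_genes <- scr$fatty_acid_oxidation$gene[
    scr$fatty_acid_oxidation$class == "significant_up"]
  expect_setequal(up_genes, c("ACADVL", "HADH", "HADHA", "HADHB"))

  scr6 <- screen_pathways(axis_fixture("table6"), load_gene_sets()[["table6"]],
                          screen_config("rnaseq"))
  ppp6 <- pathway_summary(scr6$pentose_phosphate)
  expect_equal(ppp6$n_in_set, 7)
  expect_equal(ppp6$n_up, 6)
  expect_equal(ppp6$n_down, 1)
  down6 <- scr6$pentose_phosphate$gene[scr6$pentose_phosphate$class == "significant_down"]
  expect_equal(down6, "PGLS")

  empty <- pathway_summary(scr$carnitine_shuttle)
  expect_equal(empty$n_in_set, 0)
  expect_equal(empty$n_up + empty$n_down + empty$n_low, 0)
})

test_that("multi-tissue records screen per tissue", {
  records <- axis_fixture("table4")
  sets <- load_gene_sets()[["table4_liver"]]
  scr <- screen_pathways(records, sets, screen_config("microarray"),
                         tissue = "liver")
  expect_equal(scr$fatty_acid_synthesis$class[
    scr$fatty_acid_synthesis$gene == "SCD"], "significant_down")
  scr_a <- screen_pathways(records, load_gene_sets()[["table4_adipose"]],
                           screen_config("microarray"), tissue = "adipose")
  expect_equal(scr_a$fatty_acid_synthesis$class[
    scr_a$fatty_acid_synthesis$gene == "SCD"], "significant_up")
})

test_that("bracketed regulator entries map to the low-expression class", {
  t3 <- axis_fixture("table3")
  rnaseq_rows <- t3[t3$condition %in% c("mpp", "metformin"), ]
  # bracketed entries denote baseline < 1 RPKM; surrogate baselines encode
  # the bracket flag
  baseline <- ifelse(rnaseq_rows$low_expression, 0.5, 10)
  cls <- classify_gene(rnaseq_rows$fold_change, rnaseq_rows$p_value,
                       baseline, screen_config("rnaseq"))
  expect_true(all(cls[rnaseq_rows$low_expression] == "low_expression"))
  bold <- rnaseq_rows$significant & !rnaseq_rows$low_expression
  expect_true(all(cls[bold] %in% c("significant_up", "significant_down")))
  plain <- !rnaseq_rows$significant & !rnaseq_rows$low_expression
  expect_true(all(cls[plain] == "not_significant"))
})

test_that("lactate/pyruvate ratios reproduce the printed cells", {
  met <- read_metabolite_table()
  liver <- lp_ratio(met, "liver")
  expect_equal(liver$rounded, 1.63)    # 0.70 / 0.43
  muscle <- lp_ratio(met, "muscle")
  expect_equal(muscle$rounded, 0.86)   # 0.96 / 1.11
  serum <- lp_ratio(met, "serum")
  expect_equal(serum$rounded, 3.71)    # 0.89 / 0.24
  # printed cells agree with the recomputation
  printed <- met[met$metabolite == "L/P ratio", ]
  for (tis in printed$tissue)
    expect_equal(lp_ratio(met, tis)$rounded,
                 printed$fold_change[printed$tissue == tis], info = tis)
  # pyruvate was not detected in adipose tissue
  expect_error(lp_ratio(met, "adipose"), "undefined")
  # equal fold changes give exactly 1
  toy <- data.frame(metabolite = c("Lactate", "Pyruvate"),
                    tissue = "t", fold_change = c(0.5, 0.5))
  expect_equal(lp_ratio(toy, "t")$rounded, 1.00)
})

test_that("screening is deterministic: identical inputs, identical tables", {
  records <- axis_fixture("table2")
  sets <- load_gene_sets()[["table2"]]
  a <- screen_pathways(records, sets, screen_config("rnaseq"))
  b <- screen_pathways(records, sets, screen_config("rnaseq"))
  expect_identical(lapply(a, identity), lapply(b, identity))
})
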