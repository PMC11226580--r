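# Shipped pathway definitions: per-pathway reference ledgers, citrate
# shuttle variants, C16-exact mode, chain-length convergence and the curated
# gene sets.

entry <- function(l, sp) as.numeric(ledger_entry(l, sp))

test_that("idealized pathway ledgers match their reference stoichiometries", {
  ppp <- get_pathway("ppp", "idealized")$ledger
  expect_equal(entry(ppp, "ATP"), -1)
  expect_equal(entry(ppp, "NADPH"), 12)
  expect_equal(entry(ppp, "glucose"), -1)
  expect_equal(entry(ppp, "CO2"), 6)

  fas <- get_pathway("fa_synthesis", "idealized")$ledger
  expect_equal(entry(fas, "ATP"), -1)
  expect_equal(entry(fas, "NADPH"), -2)

  expect_equal(length(get_pathway("carnitine_shuttle")$ledger), 0L)

  box <- get_pathway("beta_oxidation", "idealized")$ledger
  expect_equal(entry(box, "NADH"), 1)
  expect_equal(entry(box, "FADH2"), 1)

  shuttle <- get_pathway("citrate_shuttle", "idealized")$ledger
  expect_equal(entry(shuttle, "ATP"), -2)
  expect_equal(entry(shuttle, "NADH"), -1)
  expect_equal(entry(shuttle, "NADPH"), 1)

  std <- get_pathway("glycolysis_tca", "idealized")$ledger
  expect_equal(entry(std, "ATP"), 4)
  expect_equal(entry(std, "NADH"), 10)
  expect_equal(entry(std, "FADH2"), 2)

  keto <- get_pathway("ketogenesis")$ledger
  expect_equal(entry(keto, "AcCoA"), -2)
  expect_equal(entry(keto, "NADH"), -1)
  expect_equal(entry(keto, "BHB"), 1)
})

test_that("exact C16 cycling ledger matches the brute-force step summation", {
  # independent oracle: walk the palmitate cycle step by step in plain
  # arithmetic -- 7 ACACA activations, 14 FASN NADPH reductions, 7
  # beta-oxidation rounds, 8 citrate-shuttle exports
  oracle <- c(ATP = 0, NADPH = 0, NADH = 0, FADH2 = 0)
  oracle["ATP"] <- oracle["ATP"] - 7            # malonyl-CoA activations
  oracle["NADPH"] <- oracle["NADPH"] - 14       # FASN reductive steps
  for (round in 1:7) {
    oracle["NADH"] <- oracle["NADH"] + 1
    oracle["FADH2"] <- oracle["FADH2"] + 1
  }
  for (export in 1:8) {
    oracle["ATP"] <- oracle["ATP"] - 2
    oracle["NADH"] <- oracle["NADH"] - 1
    oracle["NADPH"] <- oracle["NADPH"] + 1
  }
  expect_equal(oracle, c(ATP = -23, NADPH = -6, NADH = -1, FADH2 = 7))

  l <- get_pathway("fa_cycling", "exact_c16")$ledger
  for (sp in names(oracle))
    expect_equal(entry(l, sp), unname(oracle[sp]), info = sp)
  expect_equal(entry(l, "AcCoA"), 0)           # substrate-neutral cycle
  # optional re-activation charge adds exactly 2 ATP
  l2 <- get_pathway("fa_cycling", "exact_c16", acsl_activation = TRUE)$ledger
  expect_equal(entry(l2, "ATP"), -25)
  expect_error(get_pathway("glycolysis_tca", "exact_c16"), "exact_c16")
})

test_that("per-acetyl-CoA costs converge to the idealized values with chain length", {
  ideal <- c(ATP = -3, NADPH = -1, FADH2 = 1)
  prev_err <- Inf
  for (n in c(16, 32, 64, 256)) {
    l <- fa_cycling_cn_ledger(n)
    per <- c(ATP = entry(l, "ATP"), NADPH = entry(l, "NADPH"),
             FADH2 = entry(l, "FADH2")) / (n / 2)
    err <- max(abs(per - ideal))
    expect_lt(err, prev_err)
    prev_err <- err
  }
  expect_lt(prev_err, 0.02)  # C256 is within 2% of the idealized limit
  # closed forms: per-acetyl ATP = -(3m-1)/m for m acetyl units
  m <- 8
  l16 <- fa_cycling_cn_ledger(16)
  expect_true(ledger_entry(l16, "ATP") == rat(-(3 * m - 1)))
})

test_that("citrate shuttle variants: malate equals the default, PEP avoids NADH import", {
  mal <- citrate_shuttle_variant("malate")$ledger
  def <- get_pathway("citrate_shuttle", "idealized")$ledger
  for (sp in union(mal$species, def$species))
    expect_true(ledger_entry(mal, sp) == ledger_entry(def, sp), info = sp)
  pep <- citrate_shuttle_variant("PEP")$ledger
  expect_equal(entry(pep, "NADH"), 0)
  expect_equal(entry(pep, "ATP") + entry(pep, "GTP"), -2)
  expect_true(all(pair_closure_residuals(pep)$residual_numeric == 0))
  expect_error(citrate_shuttle_variant("succinate"))
})

test_that("curated gene sets return the printed symbols in printed order", {
  expect_equal(gene_set("pentose_phosphate", "table2"),
               c("G6PD", "PGLS", "PGD", "TKT"))
  expect_equal(gene_set("citrate_shuttle", "table6"),
               c("CS", "ACLY", "MDH2", "MPC1", "PC"))
  expect_equal(gene_set("regulators", "table3_regulators"),
               c("BRCA1", "MID1IP1", "ACACB", "CD36", "LDLR", "VLDLR",
                 "FGF21", "GDF15"))
  expect_equal(gene_set("carnitine_shuttle", "table2"), character(0))
  expect_error(gene_set("no_such_pathway", "table2"), "unknown pathway")
})

test_that("gene-set overlaps are exactly the junction enzymes printed twice", {
  # the source tables print a few junction enzymes under two headings;
  # everything else partitions cleanly
  expect_setequal(gene_set_overlaps("table2")$gene, c("CS", "MDH2"))
  expect_setequal(gene_set_overlaps("table6")$gene, c("CS", "MDH2"))
  expect_setequal(gene_set_overlaps("table4_liver")$gene, "ME1")
  expect_equal(nrow(gene_set_overlaps("table4_adipose")), 0L)
  expect_equal(nrow(gene_set_overlaps("table4_muscle")), 0L)
  expect_equal(nrow(gene_set_overlaps("table3_regulators")), 0L)
})

test_that("library files load with validation and alias canonicalization", {
  lib <- axis_library()
  expect_s3_class(lib, "axis_library")
  # a user file spelling NADP+ and FADH_2 resolves onto the canonical ids
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    species = list(
      list(id = "NADP+", kind = "cofactor", conjugate_of = "NADPH", electrons_carried = 0),
      list(id = "NADPH", kind = "cofactor", conjugate_of = "NADP+", electrons_carried = 2)),
    reactions = list(list(id = "rx", name = "toy",
                          stoich = list(`NADP+` = -1, NADPH = 1))),
    pathways = list()), f, auto_unbox = TRUE)
  lib2 <- load_reaction_library(f)
  expect_true("NADP" %in% lib2$species$id)
  expect_equal(as.numeric(ledger_entry(lib2$reactions$rx$ledger, "NADPH")), 1)
  # a file distinguishing the two spellings as separate species is flagged
  jsonlite::write_json(list(
    species = list(
      list(id = "NADP", kind = "cofactor"),
      list(id = "NADP+", kind = "cofactor")),
    reactions = list(list(id = "rx", stoich = list(NADP = 1))),
    pathways = list()), f, auto_unbox = TRUE)
  expect_error(load_reaction_library(f), "spellings")
  # closure violations in a loaded file are rejected
  jsonlite::write_json(list(
    species = list(
      list(id = "ATP", kind = "cofactor", conjugate_of = "ADP"),
      list(id = "ADP", kind = "cofactor", conjugate_of = "ATP")),
    reactions = list(list(id = "leaky", stoich = list(ATP = -1))),
    pathways = list()), f, auto_unbox = TRUE)
  expect_error(load_reaction_library(f), "closure")
  unlink(f)
})

test_that("pathway nesting is depth-limited and cycle-checked", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    species = list(list(id = "X", kind = "carbon-metabolite")),
    reactions = list(list(id = "rx", stoich = list(X = 1))),
    pathways = list(
      list(id = "a", terms = list(list("b", 1))),
      list(id = "b", terms = list(list("a", 1))))), f, auto_unbox = TRUE)
  lib <- load_reaction_library(f)
  expect_error(net_ledger(composition("a", 1), lib), "cyclic")
  jsonlite::write_json(list(
    species = list(list(id = "X", kind = "carbon-metabolite")),
    reactions = list(list(id = "rx", stoich = list(X = 1))),
    pathways = list(
      list(id = "p1", terms = list(list("rx", 1))),
      list(id = "p2", terms = list(list("p1", 1))),
      list(id = "p3", terms = list(list("p2", 1))),
      list(id = "p4", terms = list(list("p3", 1))))), f, auto_unbox = TRUE)
  lib <- load_reaction_library(f)
  expect_equal(as.numeric(ledger_entry(net_ledger(composition("p3", 1), lib), "X")), 1)
  expect_error(net_ledger(composition("p4", 1), lib), "nesting")
  unlink(f)
})
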