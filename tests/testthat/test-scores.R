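test_that("extended GMT and drug TSV round-trip through their writers", {
  db <- structure(list(
    PW1 = data.frame(gene = c("gA", "gB"), role = c(1, -1),
                     stringsAsFactors = FALSE),
    PW2 = data.frame(gene = "gC", role = 1, stringsAsFactors = FALSE)),
    class = "PathwayDB")
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_pathway_gmt(db, tf)
  db2 <- read_pathway_gmt(tf)
  expect_equal(db2$PW1$gene, c("gA", "gB"))
  expect_equal(db2$PW1$role, c(1, -1))
  # plain GMT members default to activator role
  writeLines("PWx\tdesc\tg1\tg2", tf)
  expect_equal(read_pathway_gmt(tf)$PWx$role, c(1, 1))
  ddb <- structure(list(D1 = list(targets = c("gA", "gB"),
                                  pathways = "PW1"),
                        D2 = list(targets = "gC", pathways = character(0))),
                   class = "DrugTargetDB")
  td <- withr::local_tempfile(fileext = ".tsv")
  write_drug_db(ddb, td)
  ddb2 <- read_drug_db(td)
  expect_equal(ddb2$D1$targets, c("gA", "gB"))
  expect_length(ddb2$D2$pathways, 0)
})

test_that("log fold change is case minus control median, translation
           invariant", {
  controls <- em(cbind(c(5, 1), c(7, 3), c(6, 10)), genes = c("gA", "gB"))
  case <- stats::setNames(c(8, 3), c("gA", "gB"))
  lfc <- log_fold_change(case, controls)
  expect_equal(unname(lfc$values), c(8 - 6, 3 - 3))
  # case equal to the control medians gives all-zero LFC
  lfc0 <- log_fold_change(stats::setNames(c(6, 3), c("gA", "gB")), controls)
  expect_equal(unname(lfc0$values), c(0, 0))
  # adding a constant to case and every control leaves LFC unchanged
  lfc_c <- log_fold_change(case + 4, em(unclass(controls) + 4,
                                        genes = c("gA", "gB")))
  expect_equal(lfc_c$values, lfc$values)
  expect_error(log_fold_change(stats::setNames(1, "gZ"), controls),
               "gene list")
})

test_that("pathway activation averages role-weighted LFCs", {
  mk_lfc <- function(vals, genes) log_fold_change(
    stats::setNames(vals, genes),
    em(matrix(0, length(genes), 2), genes = genes))
  db <- structure(list(
    p_cancel = data.frame(gene = c("g1", "g2"), role = c(1, 1)),
    p_oppose = data.frame(gene = c("g1", "g2"), role = c(1, -1)),
    p_gone = data.frame(gene = "absent", role = 1)),
    class = "PathwayDB")
  lfc <- mk_lfc(c(1, -1), c("g1", "g2"))
  pal <- pathway_activation(lfc, db)
  expect_equal(unname(pal$values["p_cancel"]), 0)
  expect_equal(unname(pal$values["p_oppose"]), 1)
  expect_false("p_gone" %in% pal$ids)   # no surviving member -> dropped
  pal0 <- pathway_activation(mk_lfc(c(0, 0), c("g1", "g2")), db)
  expect_equal(max(abs(pal0$values)), 0)
})

test_that("BES combines pathway and target terms and is linear in LFC", {
  genes <- c("g1", "g2", "g3")
  lfc <- log_fold_change(stats::setNames(c(2, 2, 4), genes),
                         em(matrix(0, 3, 2), genes = genes))
  pdb <- structure(list(PW = data.frame(gene = c("g1", "g2"),
                                        role = c(1, 1))),
                   class = "PathwayDB")
  pal <- pathway_activation(lfc, pdb)        # PAL = 2
  ddb <- structure(list(
    D_full = list(targets = c("g1", "g2"), pathways = "PW"),
    D_nopw = list(targets = "g3", pathways = character(0)),
    D_lost = list(targets = "absent", pathways = "PW")),
    class = "DrugTargetDB")
  bes <- drug_efficiency(pal, lfc, ddb)
  expect_equal(unname(bes$values["D_full"]), 0.5 * 2 + 0.5 * 2)
  expect_equal(unname(bes$values["D_nopw"]), 4)  # target-only fallback
  expect_identical(attr(bes, "unscored"), "D_lost")
  # negating every LFC (and hence PAL) negates every BES
  lfc_neg <- log_fold_change(stats::setNames(-c(2, 2, 4), genes),
                             em(matrix(0, 3, 2), genes = genes))
  bes_neg <- drug_efficiency(pathway_activation(lfc_neg, pdb), lfc_neg, ddb)
  expect_equal(bes_neg$values, -bes$values)
  # scaling LFC scales PAL and BES by the same factor (slope propagation)
  lfc_sc <- log_fold_change(stats::setNames(3 * c(2, 2, 4), genes),
                            em(matrix(0, 3, 2), genes = genes))
  bes_sc <- drug_efficiency(pathway_activation(lfc_sc, pdb), lfc_sc, ddb)
  expect_equal(bes_sc$values, 3 * bes$values)
})

test_that("survival report flags full-target drugs and >75% pathways", {
  ddb <- structure(list(D1 = list(targets = c("a", "b"), pathways = NULL),
                        D2 = list(targets = c("a", "d"), pathways = NULL)),
                   class = "DrugTargetDB")
  surv <- c("a", "b", "c")
  rep_d <- target_survival_report(ddb, surv)
  expect_true(rep_d$table$all_survived[rep_d$table$id == "D1"])
  expect_equal(rep_d$table$fraction[rep_d$table$id == "D2"], 0.5)
  expect_equal(rep_d$pct_entries_ok, 50)
  pdb <- structure(list(P4 = data.frame(gene = c("a", "b", "c", "d"),
                                        role = 1)),
                   class = "PathwayDB")
  rep_p <- target_survival_report(pdb, surv)
  expect_equal(rep_p$table$fraction, 0.75)
  expect_false(rep_p$table$over_75)    # strictly greater than 75% required
  # invariant to gene list order
  rep_p2 <- target_survival_report(pdb, rev(surv))
  expect_equal(rep_p$table, rep_p2$table)
})

test_that("drug ranking sorts by BES with lexicographic ties", {
  genes <- c("gx", "gy", "gz", "ga", "gb")
  lfc <- log_fold_change(stats::setNames(c(3, 1, 2, 1, 1), genes),
                         em(matrix(0, 5, 2), genes = genes))
  ddb <- structure(list(x = list(targets = "gx", pathways = character(0)),
                        y = list(targets = "gy", pathways = character(0)),
                        z = list(targets = "gz", pathways = character(0)),
                        b = list(targets = "gb", pathways = character(0)),
                        a = list(targets = "ga", pathways = character(0))),
                   class = "DrugTargetDB")
  pal <- structure(list(level = "pathway_PAL", ids = character(0),
                        values = stats::setNames(numeric(0), character(0))),
                   class = "ScoreVector")
  bes <- drug_efficiency(pal, lfc, ddb)
  expect_identical(rank_drugs(bes, 2), c("x", "z"))
  expect_identical(rank_drugs(bes, 4), c("x", "z", "a", "b"))  # tie a < b
  expect_identical(rank_drugs(bes, 99), c("x", "z", "a", "b", "y"))
})
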