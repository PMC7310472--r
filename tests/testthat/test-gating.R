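test_that("default table enumerates 37 subpopulations forming a tree", {
  defs <- default_phenotypes()
  expect_length(enumerated_phenotypes(defs), 37L)
  ## every parent exists in the same tube and the table is acyclic
  for (tube in c("trucount", "falcon")) {
    d <- defs[defs$tube == tube, ]
    expect_true(all(is.na(d$parent) | d$parent %in% d$phenotype))
    expect_silent(immunofrail:::topo_order(d))
    ## roots are the CD45+ leukocyte gate
    expect_identical(d$phenotype[is.na(d$parent)], "leukocytes")
  }
})

test_that("single events land in the phenotypes their markers dictate", {
  ## side-scatter bright, CD45 dim -> neutrophil
  ev <- one_event("trucount", SSC = band["bright"], CD45 = band["dim"],
                  CD16 = band["bright"])
  res <- classify_events(ev)
  expect_equal(unname(res$counts["neutrophils"]), 1L)
  expect_equal(unname(res$counts["monocytes"]), 0L)

  ## CD4 T cell with CCR7+ CD45RA+ -> naive CD4
  ev <- one_event("falcon", SSC = band["neg"], CD45 = band["bright"],
                  CD3 = band["bright"], CD4 = band["bright"],
                  CCR7 = band["bright"], CD45RA = band["bright"])
  res <- classify_events(ev)
  expect_equal(unname(res$counts["cd4_naive"]), 1L)
  expect_equal(unname(res$counts["cd4_cm"]), 0L)

  ## CCR7- CD45RA+ CD8 T cell with CD27- CD28- -> late-stage CD8 TemRA
  ev <- one_event("falcon", SSC = band["neg"], CD45 = band["bright"],
                  CD3 = band["bright"], CD8 = band["bright"],
                  CD45RA = band["bright"])
  res <- classify_events(ev)
  expect_equal(unname(res$counts["cd8_temra"]), 1L)
  expect_equal(unname(res$counts["cd8_temra_late"]), 1L)
  expect_equal(unname(res$counts["cd8_temra_early"]), 0L)
})

test_that("ties exactly at a threshold fall in the higher band", {
  th <- default_thresholds()
  low <- th$low[th$channel == "CD16"][1]
  high <- th$high[th$channel == "CD16"][1]
  ev <- one_event("trucount", SSC = band["dim"], CD45 = band["dim"],
                  CD16 = low)
  res <- classify_events(ev)  # CD16 == low cut: positive, not negative
  expect_equal(unname(res$counts["monocytes_cd16pos"]), 1L)
  expect_equal(unname(res$counts["monocytes_cd16neg"]), 0L)
  ev$CD16 <- high  # == high cut: bright band (still positive)
  res <- classify_events(ev)
  expect_equal(unname(res$counts["monocytes_cd16pos"]), 1L)
})

test_that("classification on labeled synthetic events is near perfect and
           tree-consistent", {
  tubes <- make_labeled_tubes()
  defs <- default_phenotypes()
  map <- phenotype_leaf_map()
  for (tube in c("trucount", "falcon")) {
    ev <- if (tube == "trucount") tubes$tru else tubes$fal
    labels <- ev$.label
    res <- classify_events(ev[, setdiff(names(ev), ".label")], defs,
                           tube = tube)
    d <- defs[defs$tube == tube, ]
    ## child never exceeds parent and is a subset of it
    for (i in which(!is.na(d$parent))) {
      expect_true(all(res$membership[[d$phenotype[i]]] %in%
                        res$membership[[d$parent[i]]]))
    }
    ## per-phenotype accuracy vs generator truth >= 99%
    for (ph in d$phenotype[d$primary]) {
      truth <- which(labels %in% map[[ph]])
      if (length(truth) < 50) next
      hits <- res$membership[[ph]]
      acc <- length(intersect(hits, truth)) / length(truth)
      expect_gt(acc, 0.99)
      fdr <- 1 - length(intersect(hits, truth)) / max(1, length(hits))
      expect_lt(fdr, 0.01)
    }
    ## CD4 / CD8 / CD56+ T branches are disjoint
    expect_length(intersect(res$membership[["t_cd4"]],
                            res$membership[["t_cd8"]]), 0)
    expect_length(intersect(res$membership[["t_cd4"]],
                            res$membership[["t_cd56pos"]]), 0)
  }
})

test_that("memory T partition is exact and stages only Tem/TemRA", {
  set.seed(20)
  ## exhaustive CCR7/CD45RA/CD27/CD28 combinations
  states <- expand.grid(CCR7 = c(band["neg"], band["bright"]),
                        CD45RA = c(band["neg"], band["bright"]),
                        CD27 = c(band["neg"], band["bright"]),
                        CD28 = c(band["neg"], band["bright"]))
  part <- memory_t_partition(states)
  expect_equal(sum(table(part$subset)), nrow(states))  # exact partition
  expect_identical(
    as.character(part$subset[states$CCR7 > 100 & states$CD45RA < 100]),
    rep("cm", 4))
  ## CD27+CD28- Tem is neither early nor late
  tem_mixed <- states$CCR7 < 100 & states$CD45RA < 100 &
    states$CD27 > 100 & states$CD28 < 100
  expect_identical(as.character(part$stage[tem_mixed]), "other")
  ## naive and cm carry no stage
  expect_true(all(is.na(part$stage[part$subset %in% c("naive", "cm")])))
})

test_that("B and NK labels follow the CD19/CD38/CD27 and CD56/CD16 rules", {
  ev <- rbind(
    one_event("trucount", CD45 = band["bright"], CD19 = band["bright"],
              CD38 = band["dim"], CD27 = band["bright"]),   # memory B
    one_event("trucount", CD45 = band["bright"],
              CD56 = band["bright"]),                       # CD56bright NK
    one_event("trucount", CD45 = band["bright"], CD3 = band["bright"],
              CD56 = band["dim"]))                          # CD56+ T
  lab <- b_nk_partition(ev)
  expect_identical(lab, c("b_memory", "nk_cd56bright_cd16neg",
                          "t_cd56pos"))
})

test_that("marker expression summaries behave at the edges", {
  tubes <- make_labeled_tubes(seed = 77, frac = 0.02)
  res <- classify_events(tubes$tru[, setdiff(names(tubes$tru), ".label")],
                         tube = "trucount")
  ## lognormal(6, 0.25) sample median ~ e^6 on neutrophil CD16
  med <- marker_expression_summary(res, "neutrophils", "CD16")
  expect_lt(abs(log(med) - 6), 0.1)
  ## empty gate -> missing, not zero
  empty <- classify_events(one_event("trucount", SSC = band["bright"],
                                     CD45 = band["dim"]),
                           tube = "trucount")
  expect_identical(marker_expression_summary(empty, "b_cells", "CD38"),
                   NA_real_)
  ## all-equal intensities -> that value
  ev <- one_event("trucount", SSC = band["bright"], CD45 = band["dim"])
  ev <- rbind(ev, ev)
  ev$CD16 <- 123
  r2 <- classify_events(ev, tube = "trucount")
  expect_equal(marker_expression_summary(r2, "neutrophils", "CD16"), 123)
  ## unknown channel errors by name
  expect_error(marker_expression_summary(res, "neutrophils", "CD99"),
               "CD99")
})

test_that("missing channels are reported with channel and phenotype", {
  ev <- one_event("trucount", SSC = band["bright"], CD45 = band["dim"])
  ev$CD16 <- NULL
  expect_error(classify_events(ev, tube = "trucount"),
               "CD16.*monocytes_cd16neg|monocytes_cd16neg.*CD16")
})

test_that("HLA-DR sensitivity filter is idempotent, monotone, and removes
           HLA-DR negative contaminants", {
  defs <- default_phenotypes()
  f1 <- hladr_sensitivity_filter(defs)
  expect_identical(f1, hladr_sensitivity_filter(f1))  # idempotent
  expect_identical(f1$gate[f1$phenotype == "neutrophils"],
                   defs$gate[defs$phenotype == "neutrophils"])

  tubes <- make_labeled_tubes(seed = 55, frac = 0.02)
  ev <- tubes$tru[, setdiff(names(tubes$tru), ".label")]
  ## spike in HLA-DR negative events that otherwise look like monocytes
  spike <- ev[immunofrail:::eval_predicate(ev, "SSC", "dim",
                                           default_thresholds()), ][1:20, ]
  spike$HLADR <- band["neg"]
  spike$CD3 <- band["neg"]; spike$CD19 <- band["neg"]
  spike$CD45 <- band["dim"]; spike$SSC <- band["dim"]
  ev2 <- rbind(ev, spike)
  before <- classify_events(ev2, defs, tube = "trucount")
  after <- classify_events(ev2, f1, tube = "trucount")
  expect_lte(after$counts[["monocytes"]], before$counts[["monocytes"]])
  expect_equal(before$counts[["monocytes"]] - after$counts[["monocytes"]],
               20L)
})
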