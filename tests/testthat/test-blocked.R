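test_that("native blocked metabolites match ground truth on the toys", {
  expect_equal(nrow(blocked_metabolites(t1_model())), 0)
  expect_setequal(blocked_metabolites(t2_model())$id, c("Fred", "Fox"))
  expect_setequal(blocked_metabolites(t3()$model)$id, c("THF", "fTHF"))
})

test_that("blocked reactions are a bare-network property by default", {
  m <- t1_model()
  # the chain dead-ends in A3, so without drains nothing can run
  expect_setequal(blocked_reactions(m)$id, c("EX_A1", "R1", "R2"))
  # with instrumentation sinks in place the native chain is fully active
  expect_equal(nrow(blocked_reactions(add_sinks(m), with_sinks = TRUE)), 0)
  ko <- knockout_genes(add_sinks(m), "g1")
  expect_setequal(blocked_reactions(ko, with_sinks = TRUE)$id, c("R1", "R2"))
  # a reaction pinned to zero bounds is always blocked
  dis <- delete_reactions(t2_model(), "R1")
  expect_true("R1" %in% blocked_reactions(dis)$id)
})

test_that("knockout deltas are after-minus-before footprints", {
  m <- t1_model()
  expect_setequal(knockout_delta(m, "g1")$id, c("A2", "A3"))
  expect_equal(nrow(knockout_delta(m, "g2")), 0)

  fx <- t3()
  for (g in names(fx$spec$knockout_deltas)) {
    expect_setequal(knockout_delta(fx$model, g)$id, fx$spec$knockout_deltas[[g]])
  }
})

test_that("deficiency delta reproduces the folate-analog footprint", {
  fx <- t3()
  delta <- deficiency_delta(fx$model, fx$spec$folate_species)
  expect_setequal(delta$id, fx$spec$deficiency_delta)
  expect_equal(nrow(delta), 7)
  # a pool with no consumers is the identity perturbation
  expect_warning(none <- deficiency_delta(t1_model(), "A3"), "no consuming")
  expect_equal(nrow(none), 0)
})

test_that("deltas are disjoint from the native blocked set and nest monotonically", {
  fx <- t3()
  native <- blocked_metabolites(fx$model)
  for (g in c("gGART", "gATIC", "gSAM")) {
    d <- knockout_delta(fx$model, g, native = native)
    expect_length(intersect(d$id, native$id), 0)
    after <- blocked_metabolites(knockout_genes(fx$model, g))
    expect_true(all(d$id %in% after$id))
  }
  # G subset H implies delta(G) subset delta(H)
  small <- knockout_delta(fx$model, "gADE")
  big <- knockout_delta(fx$model, c("gADE", "gGUA"))
  expect_true(all(small$id %in% big$id))
  bigger <- knockout_delta(fx$model, c("gADE", "gGUA", "gPPAT"))
  expect_true(all(big$id %in% bigger$id))
})

test_that("cofactor-strip rescue restores SAM under folate deficiency", {
  fx <- t3()
  m <- fx$model
  # deficiency alone blocks the SAM analog
  expect_true("SAM" %in% deficiency_delta(m, fx$spec$folate_species)$id)
  # strip folate from the two dependent steps, exempt them from blockade
  stripped <- strip_cofactor(m, fx$spec$folate_steps, list(c("fTHF", "THF")))
  rescued <- suppressWarnings(
    deficiency_delta(stripped, fx$spec$folate_species,
                     exclude_reactions = fx$spec$folate_steps))
  expect_false("SAM" %in% rescued$id)
  sunk <- suppressWarnings(
    block_consumers(add_sinks(stripped), fx$spec$folate_species,
                    exclude_reactions = fx$spec$folate_steps))
  expect_gt(max_production(sunk, "SAM"), 1e-6)
})

test_that("production profiles and reductions follow the chain", {
  m <- t1_model()
  s <- add_sinks(m)
  native <- production_profile(s)
  expect_equal(stats::setNames(native$production, native$metabolite),
               c(A1 = 10, A2 = 10, A3 = 10))
  ko <- production_profile(knockout_genes(s, "g1"), label = "ko:g1")
  red <- reduction_profile(native, ko)
  expect_equal(stats::setNames(red$reduction, red$metabolite),
               c(A1 = 0, A2 = 1, A3 = 1))
  # natively blocked metabolites have reduction 0 by convention
  t2s <- add_sinks(t2_model())
  nat2 <- production_profile(t2s)
  ko2 <- production_profile(knockout_genes(t2s, "g1"), label = "ko:g1")
  red2 <- reduction_profile(nat2, ko2)
  expect_equal(red2$reduction[red2$metabolite == "Fred"], 0)
})

test_that("the all-gene scan equals naive per-gene evaluation", {
  for (fx in list(list(model = t1_model()), t3())) {
    m <- fx$model
    scan <- scan_all_genes(m)
    naive <- scan_all_genes(m, dedupe = FALSE)
    expect_equal(scan$gene, naive$gene)
    expect_equal(scan$blocked, naive$blocked)
    native <- blocked_metabolites(m)
    for (i in seq_len(nrow(scan))) {
      expect_setequal(scan$blocked[[i]],
                      knockout_delta(m, scan$gene[i], native = native)$id)
    }
  }
})

test_that("scan summary reports the empty-footprint fraction", {
  scan <- scan_all_genes(t1_model())
  expect_equal(sort(scan$gene), c("g1", "g2", "g3"))
  expect_setequal(scan$blocked[[which(scan$gene == "g1")]], c("A2", "A3"))
  g <- glance(scan)
  expect_equal(g$n_nonempty, 1)
  expect_equal(g$fraction_empty, 2 / 3)
  # a gene absent from every GPR has no footprint
  m <- t1_model()
  m$genes <- c(m$genes, "gNOWHERE")
  s2 <- scan_all_genes(m)
  expect_equal(s2$n_blocked[s2$gene == "gNOWHERE"], 0)
})

test_that("compartment collapse groups species by base id", {
  mets <- tibble::tibble(id = c("sam_c", "sam_m", "atp_c"),
                         compartment = c("c", "m", "c"))
  rxn <- tibble::tibble(id = "EX_sam", stoich = list(c(sam_c = 1)),
                        lb = 0, ub = 0, gpr = "")
  m <- metabolic_model(mets, rxn)
  bs <- blocked_metabolites(m)
  coll <- collapse_compartments(bs, m)
  expect_equal(coll$n_species[coll$base_id == "sam"], 2)
  expect_equal(coll$n_species[coll$base_id == "atp"], 1)
})
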