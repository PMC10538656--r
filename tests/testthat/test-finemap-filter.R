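mk_cs <- function(cs_id, variants, z = 5, pip = 0.5, trait = NULL) {
  data.frame(molecular_trait_id = if (is.null(trait)) cs_id else trait,
             molecular_trait_object_id = "G", cs_id = cs_id,
             variant = variants, pip = pip,
             z = rep_len(z, length(variants)), stringsAsFactors = FALSE)
}

test_that("credible-set QC uses strict z and size thresholds", {
  low <- mk_cs("a", c("chr1_1_A_G", "chr1_2_A_G"), z = c(2.1, -2.99))
  big <- mk_cs("b", sprintf("chr1_%d_A_G", 1:201), z = 10)
  edge <- mk_cs("c", sprintf("chr1_%d_A_G", 300 + 1:200), z = 3.0)
  res <- filter_credible_sets(rbind(low, big, edge))
  expect_equal(res$kept, "c")  # 200 members and max|z| = 3.0 both survive
  expect_equal(res$discarded$reason[res$discarded$cs_id == "a"], "low_z")
  expect_equal(res$discarded$reason[res$discarded$cs_id == "b"], "oversized")
  both <- mk_cs("d", sprintf("chr1_%d_A_G", 600 + 1:201), z = 1)
  res2 <- filter_credible_sets(both)
  expect_equal(res2$discarded$reason, "low_z;oversized")
})

test_that("connected components equal the pairwise-merge fixpoint oracle", {
  # A{v1,v2}, B{v2,v3}, C{v4} -> {A,B}, {C}
  cs <- rbind(mk_cs("A", c("chr1_1_A_G", "chr1_2_A_G")),
              mk_cs("B", c("chr1_2_A_G", "chr1_3_A_G")),
              mk_cs("C", "chr1_4_A_G"))
  p <- build_components(cs)
  expect_equal(lapply(p$components, `[[`, "cs_ids"),
               list(c("A", "B"), "C"))
  # disjoint singletons
  p2 <- build_components(rbind(mk_cs("A", "chr1_1_A_G"),
                               mk_cs("B", "chr1_2_A_G"),
                               mk_cs("C", "chr1_3_A_G")))
  expect_length(p2$components, 3L)
  # chain closure: A-B and B-C overlap, A-C do not, still one component
  p3 <- build_components(rbind(
    mk_cs("A", c("chr1_1_A_G", "chr1_2_A_G")),
    mk_cs("B", c("chr1_2_A_G", "chr1_3_A_G")),
    mk_cs("C", c("chr1_3_A_G", "chr1_4_A_G"))))
  expect_equal(p3$components[[1]]$cs_ids, c("A", "B", "C"))
  # random instances vs the fixpoint oracle (and igraph as a second check)
  for (seed in 1:40) {
    sets <- random_cs_instance(n_cs = sample(5:50, 1), n_var_pool = 40,
                               seed = seed)
    part <- build_components(cs_sets_to_df(sets))
    got <- lapply(part$components, `[[`, "cs_ids")
    expect_equal(got, components_fixpoint_oracle(sets))
  }
  skip_if_not_installed("igraph")
  sets <- random_cs_instance(30, 25, seed = 99)
  edges <- do.call(rbind, lapply(names(sets), function(i) {
    hits <- names(sets)[vapply(sets, function(s) {
      length(intersect(s, sets[[i]])) > 0
    }, TRUE)]
    if (length(hits)) cbind(i, hits) else NULL
  }))
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(gr)$membership
  got <- build_components(cs_sets_to_df(sets))$membership
  expect_equal(length(unique(memb)), length(unique(got)))
  # identical partitions up to labelling: same co-membership indicator
  same <- function(m) outer(m, m, "==")
  expect_equal(unname(same(memb[names(got)])), unname(same(got)))
})

test_that("partition is invariant to input row order", {
  sets <- random_cs_instance(25, 20, seed = 7)
  df <- cs_sets_to_df(sets)
  set.seed(8)
  shuffled <- df[sample.int(nrow(df)), , drop = FALSE]
  p1 <- build_components(df)
  p2 <- build_components(shuffled)
  expect_equal(p1$components, p2$components)
  expect_equal(p1$membership, p2$membership)
})

test_that("tag selection: highest member PIP wins, ties break lexically", {
  cs <- rbind(
    mk_cs("tA_L1", c("chr1_1_A_G", "chr1_2_A_G"), pip = c(0.93, 0.05),
          trait = "tA"),
    mk_cs("tB_L1", c("chr1_2_A_G", "chr1_3_A_G"), pip = c(0.88, 0.1),
          trait = "tB"))
  tags <- select_tags(build_components(cs), cs)
  expect_equal(tags$molecular_trait_id, "tA")
  expect_equal(tags$max_pip, 0.93)
  # exact tie -> lexicographically smaller trait id
  tie <- rbind(mk_cs("tZ_L1", "chr1_1_A_G", pip = 0.9, trait = "tZ"),
               mk_cs("tY_L1", "chr1_1_A_G", pip = 0.9, trait = "tY"))
  expect_equal(select_tags(build_components(tie), tie)$molecular_trait_id,
               "tY")
  # singleton component tags itself
  single <- mk_cs("tQ_L1", "chr9_5_A_G", pip = 0.4, trait = "tQ")
  expect_equal(select_tags(build_components(single),
                           single)$molecular_trait_id, "tQ")
  # distinct signals of one trait may both be tags
  two_sig <- rbind(mk_cs("tA_L1", "chr1_1_A_G", pip = 0.9, trait = "tA"),
                   mk_cs("tA_L2", "chr1_9_A_G", pip = 0.8, trait = "tA"))
  expect_equal(nrow(select_tags(build_components(two_sig), two_sig)), 2L)
})

test_that("summary-statistic filtering reports the reduction", {
  ss <- expand.grid(molecular_trait_id = paste0("t", 1:20),
                    variant = sprintf("chr1_%d_A_G", 1:1000),
                    stringsAsFactors = FALSE)
  ss$molecular_trait_object_id <- "G"
  res <- filter_sumstats(ss, "t1")
  expect_equal(res$report$rows_in, 20000)
  expect_equal(res$report$rows_out, 1000)
  expect_equal(res$report$reduction, 0.95)
  # every trait a tag -> reduction 0
  res_all <- filter_sumstats(ss, paste0("t", 1:20))
  expect_equal(res_all$report$reduction, 0)
  expect_error(filter_sumstats(ss, "absent"), "absent")
})

test_that("whole-group filter drops unfinemapped groups, keeps ge intact", {
  ss <- expand.grid(molecular_trait_id = paste0("t", 1:5),
                    variant = sprintf("chr1_%d_A_G", 1:50),
                    stringsAsFactors = FALSE)
  ss$molecular_trait_object_id <- ifelse(ss$molecular_trait_id %in%
                                           c("t1", "t2"), "G1", "G2")
  # only G1 has a surviving credible set
  cs <- mk_cs("t1_L1", c("chr1_1_A_G", "chr1_2_A_G"), pip = c(0.8, 0.1),
              trait = "t1")
  cs$molecular_trait_object_id <- "G1"
  res <- finemap_filter(ss, cs, method = "exon")
  expect_setequal(unique(res$sumstats$molecular_trait_id), "t1")
  expect_equal(res$report$rows_out, 50)
  # zero surviving credible sets in a group -> all its rows dropped
  cs_low <- cs; cs_low$z <- 1
  res0 <- finemap_filter(ss, cs_low, method = "exon")
  expect_equal(nrow(res0$sumstats), 0L)
  # gene-level statistics bypass the filter
  res_ge <- finemap_filter(ss, cs, method = "ge")
  expect_equal(res_ge$report$reduction, 0)
  expect_equal(nrow(res_ge$sumstats), nrow(ss))
})

test_that("correlated-trait groups reduce by >= 90%", {
  # 20 exon-level traits of one gene share a single causal signal
  set.seed(55)
  n <- 300
  dm <- simulate_genotypes(n, 40, maf = 0.3, seed = 56)
  g <- dm$dosage[, 20]
  ss_all <- list(); cs_all <- list()
  for (t in 1:20) {
    y <- drop(scale(g + rnorm(n, 0, 0.7)))  # shared signal, correlated traits
    recs <- nominal_scan(y, dm$dosage, molecular_trait_id = paste0("ex", t),
                         group_id = "GENE1")
    fm <- simulate_finemap_outputs(recs)
    ss_all[[t]] <- recs
    cs_all[[t]] <- fm$credible_sets
  }
  ss <- do.call(rbind, ss_all)
  cs <- do.call(rbind, cs_all)
  res <- finemap_filter(ss, cs, method = "exon")
  expect_gte(res$report$reduction, 0.9)
  expect_lte(nrow(res$tags), length(unique(cs$cs_id)))
})
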