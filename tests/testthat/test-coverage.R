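test_that("coordinate map compresses introns to a fixed width", {
  ex <- data.frame(start = c(100, 400), end = c(200, 500))
  cm <- build_coordinate_map(ex, intron_width = 50, flank = 0)
  s <- cm$segments
  expect_equal(s$target_start[s$type == "exon"], c(0, 150))
  expect_equal(s$target_end[s$type == "exon"], c(100, 250))
  expect_equal(max(s$target_end), 250)
  # single exon maps to the identity shifted by the flank
  cm1 <- build_coordinate_map(data.frame(start = 1000, end = 1200),
                              flank = 30)
  expect_equal(map_to_target(cm1, 1000:1199), 30:229)
  # a 49-bp gap still renders at the fixed width
  cm49 <- build_coordinate_map(data.frame(start = c(0, 149),
                                          end = c(100, 200)))
  expect_equal(max(cm49$segments$target_end), 100 + 50 + 51)
  expect_error(build_coordinate_map(data.frame(start = numeric(0),
                                               end = numeric(0))), "empty")
})

test_that("target length follows the exon + fixed-intron + flank formula", {
  set.seed(71)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    widths <- sample(50:200, k, replace = TRUE)
    gaps <- sample(10:500, k, replace = TRUE)
    starts <- 1000 + cumsum(gaps) + c(0, cumsum(widths))[seq_len(k)]
    ends <- starts + widths
    flank <- sample(0:100, 1)
    cm <- build_coordinate_map(data.frame(start = starts, end = ends),
                               intron_width = 50, flank = flank)
    expect_equal(max(cm$segments$target_end),
                 sum(ends - starts) + 50 * (k - 1) + 2 * flank)
    # round trip on every exonic base
    bases <- unlist(mapply(seq, starts, ends - 1, SIMPLIFY = FALSE))
    expect_equal(map_from_target(cm, map_to_target(cm, bases)), bases)
    # strictly increasing over the whole mapped range
    grid <- sort(c(bases, map_from_target(cm, 1:10)))
    tp <- map_to_target(cm, seq(min(starts), max(ends) - 1))
    expect_true(all(diff(tp) > 0))
  }
})

test_that("stratification classes, normalisation and dropping behave", {
  cov <- rbind(a = rep(4, 10), b = rep(8, 10), c = rep(2, 10))
  # identical shape, different depth: identical class means
  strat <- stratify_coverage(cov, c(0, 1, 2))
  expect_equal(unname(strat$means["0", ]), unname(strat$means["2", ]))
  expect_equal(rownames(strat$means), c("0", "1", "2"))
  # dosage 1.4 dropped and reported
  strat2 <- stratify_coverage(cov, c(0, 1.4, 2))
  expect_equal(strat2$n_dropped, 1L)
  expect_equal(rownames(strat2$means), c("0", "2"))
  expect_error(stratify_coverage(cov, c(0.5, 1.4, 1.6)), "dropped")
  # planted doubling of one exon in class 2 survives normalisation
  base <- c(rep(2, 5), rep(2, 5))
  mk <- function(mult, depth) depth * c(rep(2, 5), rep(2 * mult, 5))
  cov3 <- rbind(mk(1, 1), mk(1, 7), mk(2, 1), mk(2, 3))
  strat3 <- stratify_coverage(cov3, c(0, 0, 2, 2))
  ratio <- strat3$means["2", 6] / strat3$means["0", 6]
  flat_ratio <- strat3$means["2", 1] / strat3$means["0", 1]
  expect_gt(ratio / flat_ratio, 1.99)
  expect_lt(ratio / flat_ratio, 2.01)
})

test_that("stratified means are exactly depth-invariant", {
  set.seed(72)
  cov <- matrix(rpois(20 * 30, 10) + 1, nrow = 20)
  dos <- rbinom(20, 2, 0.4)
  s1 <- stratify_coverage(cov, dos)
  s2 <- stratify_coverage(cov * runif(20, 0.2, 5), dos)
  expect_equal(s1$means, s2$means, tolerance = 1e-12)
})

test_that("rescaled coverage aligns exonic signal on the target axis", {
  ex <- data.frame(start = c(0, 200), end = c(100, 300))
  cm <- build_coordinate_map(ex, intron_width = 50)
  # bin-5 coverage over 0..300: exon1 = 3, intron = 0, exon2 = 7
  cov <- c(rep(3, 20), rep(0, 20), rep(7, 20))
  out <- rescale_coverage(cov, 0, cm, bin = 5)
  expect_length(out, ceiling((100 + 50 + 100) / 5))
  expect_equal(out[1:20], rep(3, 20))          # exon 1 preserved
  expect_equal(out[31:50], rep(7, 20))         # exon 2 preserved
  expect_equal(unique(out[21:30]), 0)          # compressed intron
})

test_that("the rendered figure emits aligned, testable tables", {
  set.seed(73)
  n <- 60
  dm <- simulate_genotypes(n, 10, maf = 0.4, seed = 74)
  g <- setNames(dm$dosage[, 5], dm$samples)
  gene <- simulate_gene(g, effect = 2.5, depth = 800, seed = 75)
  cm <- build_coordinate_map(unique(gene$models$exons[, c("start", "end")]))
  resc <- t(apply(gene$coverage, 1, rescale_coverage,
                  cov_start = gene$span[1], cmap = cm, bin = gene$bin))
  strat <- stratify_coverage(resc, g)
  exon_std <- inverse_normal_transform(gene$exon_counts)
  prof <- exon_effect_profile(g, exon_std)
  ex_meta <- unique(gene$models$exons[gene$models$exons$transcript_id == "T1",
                                      c("start", "end")])
  prof$start <- ex_meta$start
  prof$end <- ex_meta$end
  out_prefix <- file.path(withr::local_tempdir(), "GFIX1_test")
  tabs <- render_qtl_plot(strat, prof, gene$models, cm, out_prefix)
  expect_true(file.exists(paste0(out_prefix, "_coverage.tsv")))
  expect_true(file.exists(paste0(out_prefix, "_exon_effects.tsv")))
  expect_true(file.exists(paste0(out_prefix, "_tracks.tsv")))
  expect_true(!is.null(tabs$image) && file.exists(tabs$image))
  # panel alignment: all tables live on the same target axis
  t_max <- max(cm$segments$target_end)
  expect_lte(max(tabs$coverage$target_start), t_max)
  expect_lte(max(tabs$tracks$target_end), t_max)
  expect_true(all(tabs$exon_effects$target_mid >= 0 &
                    tabs$exon_effects$target_mid <= t_max))
  # the planted exon (short in T2) carries the splicing effect
  eff <- tabs$exon_effects
  expect_true(eff$significant[eff$exon == "GFIX1_exon4"])
  # a missing panel input is tolerated
  expect_message(
    tabs2 <- render_qtl_plot(NULL, prof, gene$models, cm,
                             file.path(withr::local_tempdir(), "noA")),
    "omitted")
  expect_null(tabs2$coverage)
})
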