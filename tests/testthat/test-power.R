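test_that("ground-truth designation samples per term and unions", {
  ann <- structure(list(genes_of = list(T1 = paste0("g", 1:6),
                                        T2 = paste0("g", 4:9),
                                        T0 = character()),
                        universe = paste0("g", 1:9)),
                   class = "annotation_map")
  expect_setequal(designate_ground_truth(ann, "T1", 1), paste0("g", 1:6))
  half <- designate_ground_truth(ann, "T1", 0.5, seed = 7)
  expect_equal(length(half), 3L)
  expect_true(all(half %in% paste0("g", 1:6)))
  expect_identical(half, designate_ground_truth(ann, "T1", 0.5, seed = 7))
  both <- designate_ground_truth(ann, c("T1", "T2"), 1)
  expect_setequal(both, paste0("g", 1:9))
  expect_equal(anyDuplicated(both), 0L)
  expect_error(designate_ground_truth(ann, "T0", 1), "T0")
})

test_that("null classification follows both framework definitions", {
  uni <- paste0("g", 1:10)
  ann <- structure(list(genes_of = list(T = c("g1", "g2"),
                                        U = c("g3", "g4"),
                                        W = uni),
                        universe = uni), class = "annotation_map")
  # DE = {g1}: T has 1/2 > 0/8 inside vs outside
  expect_equal(classify_nulls(ann, "g1", "self_contained", c("T", "U")), "T")
  expect_equal(classify_nulls(ann, "g1", "competitive", c("T", "U")), "T")
  # U shares no DE gene: null under both
  expect_false("U" %in% classify_nulls(ann, "g1", "self_contained"))
  # DE = everything: self-contained non-null, competitive null (1 == 1,
  # "at most as often" is not strict)
  expect_setequal(classify_nulls(ann, uni, "self_contained", c("T", "U")),
                  c("T", "U"))
  expect_equal(length(classify_nulls(ann, uni, "competitive", c("T", "U"))), 0L)
  # whole-universe term has an empty complement: excluded from the family
  expect_false("W" %in% classify_nulls(ann, "g1", "competitive"))
})

test_that("ancestors of a fully-DE term are all self-contained non-null", {
  fx <- random_godag(30, 80, seed = 13)
  term <- sample(leaves(fx$dag), 1)
  de <- designate_ground_truth(fx$ann, term, 1)
  a1 <- classify_nulls(fx$ann, de, "self_contained")
  expect_true(all(ancestors_of(fx$dag, term) %in% a1))
})

test_that("expression simulation has the stated means, variance and determinism", {
  genes <- paste0("g", 1:500)
  de <- paste0("g", 1:50)
  # null configuration: no group difference
  d0 <- simulate_expression(genes, de, beta_effect = 0,
                            n_control = 10, n_case = 10, seed = 1)
  expect_within_se(mean(d0$matrix), 0, 1 / sqrt(length(d0$matrix)))
  # beta 5 at n = 50/50: DE-gene group mean difference near 5
  d5 <- simulate_expression(genes, de, beta_effect = 5,
                            n_control = 50, n_case = 50, seed = 2)
  diff_mean <- rowMeans(d5$matrix[de, d5$group == "case"]) -
               rowMeans(d5$matrix[de, d5$group == "control"])
  expect_within_se(mean(diff_mean), 5, sqrt(2 / 50 / length(de)))
  # non-DE genes stay centered
  other <- setdiff(genes, de)
  expect_within_se(mean(d5$matrix[other, ]), 0,
                   1 / sqrt(length(other) * 100))
  # determinism: bitwise identical on rerun
  expect_identical(d5$matrix,
                   simulate_expression(genes, de, 5, 50, 50, seed = 2)$matrix)
  # equicorrelation keeps unit marginals; the shared per-sample factor
  # dominates the sampling error of the pooled variance (n = 100 samples)
  dr <- simulate_expression(genes, de, 0, 50, 50, rho = 0.5, seed = 3)
  expect_within_se(stats::var(as.numeric(dr$matrix)), 1, 0.5 * sqrt(2 / 99))
})

test_that("gene p-values are pooled-variance two-sample t tests", {
  d <- simulate_expression(paste0("g", 1:20), character(), 0, 8, 12, seed = 4)
  p <- gene_pvalues(d)
  # dual route: agree with stats::t.test(var.equal = TRUE) per gene
  for (g in rownames(d$matrix)[1:10]) {
    ref <- stats::t.test(d$matrix[g, d$group == "case"],
                         d$matrix[g, d$group == "control"],
                         var.equal = TRUE)$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }
  # label swap leaves the two-sided p unchanged
  d_sw <- d; d_sw$group <- factor(ifelse(d$group == "case", "control", "case"),
                                  levels = c("control", "case"))
  expect_equal(gene_pvalues(d_sw), p, tolerance = 1e-12)
})

test_that("null gene p-values are uniform and separated groups give tiny p", {
  d <- simulate_expression(paste0("g", 1:1000), character(), 0, 25, 25, seed = 5)
  p <- gene_pvalues(d)
  expect_gt(stats::ks.test(p, "punif")$p.value, 1e-3)
  sep <- structure(list(
    matrix = rbind(g1 = c(0, 0.01, -0.01, 0, 1, 1.01, 0.99, 1)),
    group = factor(rep(c("control", "case"), each = 4),
                   levels = c("control", "case"))),
    class = "expression_dataset")
  expect_lt(gene_pvalues(sep)[["g1"]], 1e-6)
  # degenerate zero-variance gene: p = 1 with a warning
  flat <- structure(list(matrix = rbind(g1 = rep(3, 8)),
                         group = sep$group), class = "expression_dataset")
  expect_warning(pf <- gene_pvalues(flat), "zero pooled variance")
  expect_equal(unname(pf), 1)
})

test_that("Simes rule matches its closed form and edge cases", {
  expect_equal(simes_pvalue(0.2), 0.2)
  expect_equal(simes_pvalue(rep(0.3, 5)), 0.3)
  expect_equal(simes_pvalue(c(0.01, 0.04, 0.9)), 0.03)
  expect_error(simes_pvalue(numeric()), "at least one")
  for (i in 1:200) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(simes_pvalue(p), oracle_simes(p), tolerance = 1e-12)
  }
})

test_that("hypergeometric p-value matches exact enumeration", {
  expect_equal(hypergeom_pvalue(3, 3, 4, 10), 4 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(4, 10, 4, 10), 1)   # term = universe
  expect_error(hypergeom_pvalue(5, 3, 4, 10), "inconsistent")
  for (u in c(6, 9, 11)) {
    for (i in 1:15) {
      ts <- sample(1:u, 1); ns <- sample(1:u, 1)
      k <- sample(0:min(ts, ns), 1)
      expect_equal(hypergeom_pvalue(k, ts, ns, u),
                   oracle_hyper_enum(k, ts, ns, u), tolerance = 1e-10)
    }
  }
})

test_that("BH rejection implements the step-up rule; Bonferroni is stricter", {
  p <- c(a = 0.01, b = 0.02, c = 0.05, d = 0.8)
  expect_setequal(bh_reject(p, 0.1), c("a", "b", "c"))
  expect_equal(length(bh_reject(c(x = 1, y = 1), 0.1)), 0L)
  expect_equal(bh_reject(c(only = 0.04), 0.05), "only")
  for (i in 1:100) {
    n <- sample(1:30, 1)
    pv <- stats::setNames(stats::runif(n), paste0("t", seq_len(n)))
    q <- stats::runif(1, 0.01, 0.3)
    expect_setequal(bh_reject(pv, q), oracle_bh(pv, q))
    expect_true(all(bh_reject(pv, q, "bonferroni") %in% bh_reject(pv, q)))
  }
  # pluggable procedure
  expect_equal(bh_reject(p, 0.1, method = function(p, q) p <= 0.015), "a")
})

test_that("power and FDP follow the guarded set formulas", {
  expect_equal(power_fdp(c("t1", "t2"), c("t1", "t3")),
               c(power = 0.5, fdp = 0.5))
  expect_equal(power_fdp(character(), character()), c(power = 0, fdp = 0))
  expect_equal(power_fdp(c("a", "b"), c("a", "b")), c(power = 1, fdp = 0))
  # pure set function: invariant to relabeling
  perm <- c(t1 = "x", t2 = "y", t3 = "z")
  expect_equal(power_fdp(perm[c("t1", "t2")], perm[c("t1", "t3")]),
               c(power = 0.5, fdp = 0.5))
})

test_that("term p-values route through Simes or the hypergeometric test", {
  ann <- structure(list(genes_of = list(T1 = c("g1", "g2", "g3"),
                                        T2 = c("g4", "g5"),
                                        T0 = character()),
                        universe = paste0("g", 1:10)),
                   class = "annotation_map")
  gp <- stats::setNames(c(0.001, 0.02, 0.9, 0.5, 0.6, rep(0.4, 5)),
                        paste0("g", 1:10))
  sc <- term_pvalues(gp, ann, c("T1", "T2"), "self_contained")
  expect_equal(unname(sc["T1"]), simes_pvalue(gp[1:3]))
  expect_equal(unname(sc["T2"]), simes_pvalue(gp[4:5]))
  expect_error(term_pvalues(gp, ann, "T0", "self_contained"), "T0")

  cp <- term_pvalues(gp, ann, c("T1", "T2"), "competitive",
                     gene_threshold = 0.05)
  # significant genes: g1, g2 -> T1 overlap 2 of 2 significant
  expect_equal(unname(cp["T1"]), hypergeom_pvalue(2, 3, 2, 10))
  expect_equal(unname(cp["T2"]), hypergeom_pvalue(0, 2, 2, 10))
})

test_that("the power study is reproducible and null under zero effect", {
  fx <- random_godag(25, 60, seed = 17)
  refined <- refine_dag(fx$dag, fx$ann)
  ann <- goscape:::restrict_annotation(fx$ann, refined$term_ids)
  mid <- names(sort(term_sizes(ann)))[ceiling(length(refined$term_ids) / 2)]
  de <- designate_ground_truth(ann, mid, 1)

  r1 <- run_power_study(refined, ann, de, 10, beta_effect = 1, reps = 5,
                        framework = "self_contained", q = 0.1, seed = 99)
  r2 <- run_power_study(refined, ann, de, 10, beta_effect = 1, reps = 5,
                        framework = "self_contained", q = 0.1, seed = 99)
  expect_identical(r1$grid, r2$grid)
  expect_identical(r1$rejection_freq, r2$rejection_freq)

  # global null: no DE genes anywhere, A1 empty, power guard gives 0
  r0 <- run_power_study(refined, ann, character(), 10, beta_effect = 0,
                        reps = 5, framework = "self_contained", q = 0.1,
                        seed = 3)
  expect_equal(r0$grid$mean_power, 0)
  expect_equal(length(r0$a1), 0L)

  # report export writes TSV + JSON
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_power_report(r1, tsv = tsv, json = js)
  expect_true(file.exists(tsv) && file.exists(js))
  expect_equal(nrow(utils::read.delim(tsv)), length(r1$tested_terms))
})

test_that("BH keeps mean FDP near or below q under the global null", {
  # no signal at all: every rejection is false, BH at q must keep the
  # frequency of any rejection (hence mean FDP) at or below q
  fx <- random_godag(20, 50, seed = 23)
  refined <- refine_dag(fx$dag, fx$ann)
  ann <- goscape:::restrict_annotation(fx$ann, refined$term_ids)
  de_out <- character()   # beta 0 anyway
  rep0 <- run_power_study(refined, ann, de_out, 10, beta_effect = 0,
                          reps = 200, framework = "self_contained",
                          q = 0.1, seed = 31)
  fdp <- rep0$per_rep$fdp
  se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.1 + 3 * se)
})
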