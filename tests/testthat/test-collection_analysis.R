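test_that("percent-significant summaries are plain arithmetic over non-skipped modules", {
  res <- c(
    lapply(1:4, function(i) fake_result(paste0("m", i),
                                        full_p(degree = 0.01))),
    lapply(5:10, function(i) fake_result(paste0("m", i),
                                         full_p(degree = 0.5)))
  )
  s <- summarize_collection(res, alpha = 0.05)
  expect_equal(s$pct_degree, 40)
  expect_equal(s$n_analyzed, 10L)
  expect_equal(s$n_skipped, 0L)

  res2 <- c(res, list(fake_result("m11", skipped_reason = "size out of range")))
  s2 <- summarize_collection(res2, alpha = 0.05)
  expect_equal(s2$n_analyzed, 10L)
  expect_equal(s2$n_skipped, 1L)
  expect_equal(s2$pct_degree, 40)
})

test_that("stratified summaries split by module attributes", {
  mk <- function(i, ns, p) fake_result(paste0("t", i), full_p(degree = p),
                                       attrs = list(namespace = ns))
  res <- c(lapply(1:4, mk, ns = "biological_process", p = 0.01),
           lapply(5:8, mk, ns = "molecular_function", p = 0.5),
           lapply(9:10, mk, ns = "cellular_component", p = 0.01))
  s <- summarize_collection(res, alpha = 0.05, stratify_by = "namespace")
  expect_equal(nrow(s), 3L)
  expect_setequal(s$stratum, c("biological_process", "molecular_function",
                               "cellular_component"))
  expect_equal(s$pct_degree[s$stratum == "biological_process"], 100)
  expect_equal(s$pct_degree[s$stratum == "molecular_function"], 0)
})

test_that("an all-skipped collection reports NA percentages", {
  res <- lapply(1:3, function(i) fake_result(paste0("m", i),
                                             skipped_reason = "size out of range"))
  s <- summarize_collection(res, alpha = 0.05)
  expect_equal(s$n_analyzed, 0L)
  expect_true(is.na(s$pct_degree))
})

test_that("pooling concatenates node-level values across modules", {
  r1 <- fake_result("m1", full_p(), observed = list(degree = c(1, 2),
                                                    n_components = 2))
  r2 <- fake_result("m2", full_p(), observed = list(degree = 3,
                                                    n_components = 1))
  expect_equal(sort(pool_parameter(list(r1, r2), "degree")), c(1, 2, 3))
  expect_equal(pool_parameter(list(r1), "degree"), c(1, 2))
  expect_equal(sort(pool_parameter(list(r1, r2), "components")), c(1, 2))
  expect_error(pool_parameter(list(), "degree"), "no analyzed modules")
  skipped <- fake_result("m3", skipped_reason = "size out of range")
  expect_error(pool_parameter(list(skipped), "degree"), "no analyzed modules")
})

test_that("class comparisons match ks.test and call direction by medians", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- compare_classes(x, x)
  expect_gt(same$ks_p, 0.9)
  expect_equal(same$direction, "none")

  a <- seq(0, 5, length.out = 60)
  cmp <- compare_classes(a + 10, a, "up", "down", "degree")
  expect_lt(cmp$ks_p, 1e-10)
  expect_equal(cmp$direction, "greater")
  expect_equal(compare_classes(a, a + 10)$direction, "less")

  p <- as.numeric(1:50)
  q <- as.numeric(26:75)
  cmp2 <- compare_classes(p, q)
  expect_equal(cmp2$ks_d, oracle_dtwo(p, q), tolerance = 1e-12)
  ref <- suppressWarnings(stats::ks.test(p, q))
  expect_equal(cmp2$ks_p, ref$p.value)

  # symmetry in p, antisymmetry in direction
  expect_equal(compare_classes(p, q)$ks_p, compare_classes(q, p)$ks_p)
})

test_that("over-representation p-values equal the hypergeometric tail", {
  background <- sprintf("g%03d", 1:100)
  term_genes <- background[1:10]
  members <- c(background[1:5], background[90:94])
  ora <- ora_fisher(members, list(termA = term_genes), background)
  expect_equal(ora$p, oracle_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
  expect_equal(ora$overlap, 5L)

  # a term covering the whole background is never enriched
  ora2 <- ora_fisher(members, list(all = background), background)
  expect_equal(ora2$p, 1)

  # module fully inside an equally sized term: smallest attainable p
  ora3 <- ora_fisher(background[1:10],
                     list(t = background[1:10], empty = character()),
                     background)
  expect_equal(nrow(ora3), 1L)  # zero-coverage terms are skipped
  expect_equal(ora3$p, oracle_hyper_tail(10, 10, 100, 10), tolerance = 1e-12)
  expect_equal(ora3$p, 1 / choose(100, 10), tolerance = 1e-9)

  expect_error(ora_fisher(c("nope"), list(t = background[1:3]), background),
               "subset")
})

test_that("BH correction is applied across terms", {
  background <- sprintf("g%03d", 1:60)
  t2g <- list(a = background[1:10], b = background[11:20],
              c = background[21:30])
  ora <- ora_fisher(background[1:10], t2g, background)
  expect_equal(ora$q, stats::p.adjust(ora$p, "BH"))
})

test_that("modules are cross-classified by network and term significance", {
  res <- list(fake_result("m1", full_p(degree = 0.01)),
              fake_result("m2", full_p()),
              fake_result("m3", full_p(components = 0.001)),
              fake_result("m4", full_p()))
  sig_ora <- data.frame(term = "t", overlap = 5L, term_size = 5L,
                        module_size = 5L, background_size = 50L,
                        p = 1e-6, q = 1e-6)
  null_ora <- transform(sig_ora, p = 0.8, q = 0.8)
  ora <- list(m1 = sig_ora, m2 = sig_ora, m3 = null_ora, m4 = null_ora)
  cls <- classify_modules(res, ora, alpha = 0.05, q_alpha = 0.05)
  expect_equal(cls$label, c("net_and_go", "only_go", "only_net", "nothing"))

  expect_error(classify_modules(res, ora[1:3]), "same modules")
})

test_that("skipped modules count as not net-significant in classification", {
  res <- list(fake_result("m1", skipped_reason = "size out of range"))
  ora <- list(m1 = data.frame(term = "t", overlap = 1L, term_size = 2L,
                              module_size = 2L, background_size = 10L,
                              p = 1e-4, q = 1e-4))
  expect_equal(classify_modules(res, ora)$label, "only_go")
})

test_that("level profiles aggregate per DAG depth", {
  dag <- data.frame(child = c("t1", "t2", "t3", "t4"),
                    parent = c("root", "root", "t1", "t2"))
  ann <- term_annotation(dag, list(g = "t3"))
  obs <- list(degree = c(2, 2), clustering = c(0.5, 0.5),
              rel_betweenness = c(0.1, 0.1), n_components = 1)
  # identical modules at two terms of the same level
  res <- list(fake_result("t3", full_p(degree = 0.01), observed = obs),
              fake_result("t4", full_p(degree = 0.01), observed = obs))
  lp <- level_profile(res, ann, alpha = 0.05)
  expect_equal(nrow(lp), 1L)
  expect_equal(lp$level, 2L)
  expect_equal(lp$n_modules, 2L)
  expect_equal(lp$mean_degree, 2)
  expect_equal(lp$pct_degree, 100)
  expect_true(lp$low_support)

  # identical statistics at two different levels -> identical rows
  res2 <- list(fake_result("t1", full_p(degree = 0.01), observed = obs),
               fake_result("t3", full_p(degree = 0.01), observed = obs))
  lp2 <- level_profile(res2, ann, alpha = 0.05)
  expect_equal(nrow(lp2), 2L)
  expect_equal(lp2$mean_degree[1], lp2$mean_degree[2])
  expect_equal(lp2$pct_degree[1], lp2$pct_degree[2])

  expect_equal(nrow(level_profile(list(), ann)), 0L)
})
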