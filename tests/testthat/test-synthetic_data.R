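test_that("spec validation rejects infeasible parameters", {
  expect_error(synth_spec(mean_degree = 0.5), "mean_degree")
  expect_error(synth_spec(n_nodes = 10, mean_degree = 10), "infeasible")
  expect_error(synth_spec(internal_density = 0), "internal_density")
  expect_error(synth_spec(module_size = 2), "module_size")
})

test_that("generated scaffolds hit the requested size and are reproducible", {
  counts <- vapply(1:20, function(seed) {
    s <- generate_scaffold(synth_spec(n_nodes = 100, mean_degree = 4,
                                      seed = seed))
    igraph::ecount(s$graph)
  }, 0)
  expect_true(all(abs(counts - 200) <= 20))

  s1 <- generate_scaffold(synth_spec(n_nodes = 100, seed = 5))
  s2 <- generate_scaffold(synth_spec(n_nodes = 100, seed = 5))
  expect_equal(ppienrich:::scaffold_hash(s1), ppienrich:::scaffold_hash(s2))
})

test_that("preferential attachment is heavier-tailed than Erdos-Renyi", {
  vpa <- var(igraph::degree(generate_scaffold(
    synth_spec(n_nodes = 1000, mean_degree = 4,
               model = "preferential_attachment", seed = 2))$graph))
  ver <- var(igraph::degree(generate_scaffold(
    synth_spec(n_nodes = 1000, mean_degree = 4, model = "erdos_renyi",
               seed = 2))$graph))
  expect_gt(vpa, ver)
})

test_that("evidence tagging lets a configurable fraction survive filtering", {
  s <- generate_scaffold(synth_spec(n_nodes = 200, mean_degree = 4,
                                    evidence_frac = 0.5, seed = 9))
  ev <- igraph::E(s$graph)$evidence
  frac2 <- mean(lengths(strsplit(ev, ";")) >= 2)
  expect_gt(frac2, 0.35)
  expect_lt(frac2, 0.65)
  p <- tempfile(fileext = ".tsv")
  write_interactome(s, p)
  filt <- read_interactome(p, min_evidence = 2)
  expect_true(filt$filtered)
  expect_lt(igraph::ecount(filt$graph), igraph::ecount(s$graph))
})

test_that("planted modules reach the requested internal density", {
  s0 <- generate_scaffold(synth_spec(n_nodes = 100, mean_degree = 4,
                                     seed = 1))
  pl <- plant_module(s0, 10, 1.0, seed = 42)
  sub <- igraph::induced_subgraph(pl$scaffold$graph, pl$module$members)
  expect_equal(igraph::ecount(sub), choose(10, 2))

  # planting at the pre-existing density on the same nodes adds nothing
  pl2 <- plant_module(pl$scaffold, 10, 1.0, seed = 43,
                      members = pl$module$members)
  expect_equal(igraph::ecount(pl2$scaffold$graph),
               igraph::ecount(pl$scaffold$graph))

  # planted internal degree exceeds the scaffold mean when
  # density * (size - 1) > mean_degree
  pl3 <- plant_module(s0, 12, 0.6, seed = 44)
  sub3 <- igraph::induced_subgraph(pl3$scaffold$graph, pl3$module$members)
  expect_gt(mean(igraph::degree(sub3)),
            mean(igraph::degree(s0$graph)))
  expect_error(plant_module(s0, 10, 1.5, seed = 1), "density")
})

test_that("signature lists are uniform draws, reproducible under seed", {
  s <- generate_scaffold(synth_spec(n_nodes = 50, mean_degree = 4, seed = 1))
  all50 <- make_signature_list(s, 50, seed = 1)
  expect_setequal(all50$members, igraph::V(s$graph)$name)
  expect_identical(make_signature_list(s, 10, seed = 2)$members,
                   make_signature_list(s, 10, seed = 2)$members)
  draws <- vapply(1:10, function(i)
    paste(make_signature_list(s, 10, seed = i)$members, collapse = ","), "")
  expect_gt(length(unique(draws)), 1L)
  expect_equal(make_signature_list(s, 10, seed = 3)$collection, "signature")
})

test_that("linker modules reconnect only through the planted hub", {
  s0 <- generate_scaffold(synth_spec(n_nodes = 120, mean_degree = 4,
                                     seed = 8))
  lk <- make_linker_module(s0, 6, seed = 55)
  hub <- lk$module$attrs$linker
  expect_false(hub %in% lk$module$members)
  expect_length(lk$module$members, 12L)

  base <- build_mcn(lk$module$members, lk$scaffold, allow_external = FALSE)
  expect_equal(count_components(base), 2L)
  ext <- build_mcn(lk$module$members, lk$scaffold, allow_external = TRUE)
  expect_equal(count_components(ext), 1L)
  expect_true(hub %in% ext$external)

  # removing the hub from the scaffold severs the bridge again
  g2 <- igraph::delete_vertices(lk$scaffold$graph, hub)
  s2 <- ppienrich:::scaffold_from_graph(g2)
  ext2 <- build_mcn(lk$module$members, s2, allow_external = TRUE)
  expect_equal(count_components(ext2), 2L)
})

test_that("benchmark collections carry labelled classes and a consistent DAG", {
  spec <- synth_spec(n_nodes = 250, mean_degree = 4, module_size = 12,
                     n_modules_per_class = 20, n_linker = 0, seed = 6)
  b <- generate_benchmark_collection(spec)
  expect_length(b$modules, 40L)
  expect_equal(sort(unique(b$truth$class)), c("functional", "signature"))

  # class labels survive a GMT round trip
  p <- tempfile(fileext = ".gmt")
  mods <- lapply(b$modules, function(m) { m$attrs$class <- m$collection; m })
  write_gmt(mods, p)
  back <- read_gmt(p)
  expect_equal(vapply(back, function(m) m$attrs$class, ""),
               stats::setNames(b$truth$class, b$truth$module_id))

  # every functional module's term contains its members after propagation
  prop <- propagate_annotations(b$annotation)
  for (id in b$truth$module_id[b$truth$class == "functional"]) {
    expect_true(all(b$modules[[id]]$members %in% prop[[id]]))
    expect_true(all(b$modules[[id]]$members %in% prop[["T:root"]]))
  }

  # the collection exercises the pipeline without size skips
  set <- analyze_collection(b$modules, b$scaffold, reps = 20, seed = 2)
  expect_true(all(set$table$skipped_reason == ""))

  spec2 <- synth_spec(n_nodes = 250, mean_degree = 4, module_size = 12,
                      n_modules_per_class = 2, n_linker = 2, seed = 6)
  b2 <- generate_benchmark_collection(spec2)
  expect_length(b2$modules, 6L)
  expect_equal(sum(b2$truth$class == "linker"), 2L)
  expect_false(any(is.na(b2$truth$linker[b2$truth$class == "linker"])))
})

test_that("benchmark generation is bit-reproducible under its seed", {
  spec <- synth_spec(n_nodes = 150, mean_degree = 4, module_size = 8,
                     n_modules_per_class = 3, n_linker = 1, seed = 12)
  b1 <- generate_benchmark_collection(spec)
  b2 <- generate_benchmark_collection(spec)
  expect_equal(ppienrich:::scaffold_hash(b1$scaffold),
               ppienrich:::scaffold_hash(b2$scaffold))
  expect_identical(lapply(b1$modules, `[[`, "members"),
                   lapply(b2$modules, `[[`, "members"))
})

test_that("planted functional modules are denser than signature lists", {
  dens <- function(s, members) {
    sub <- igraph::induced_subgraph(s$graph, members)
    igraph::ecount(sub) / choose(length(members), 2)
  }
  spec <- synth_spec(n_nodes = 300, mean_degree = 4, module_size = 15,
                     internal_density = 0.3, seed = 1)
  dfun <- dsig <- numeric(50)
  s0 <- generate_scaffold(spec)
  for (i in 1:50) {
    pl <- plant_module(s0, 15, 0.3, seed = 100 + i)
    dfun[i] <- dens(pl$scaffold, pl$module$members)
    dsig[i] <- dens(s0, make_signature_list(s0, 15, seed = 200 + i)$members)
  }
  expect_gt(mean(dfun), mean(dsig))
  expect_true(all(dfun >= 0.3))
})
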