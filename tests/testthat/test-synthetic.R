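test_that("same seed gives byte-identical bundles", {
  cfg <- synthetic_config(n_nodes = 80, n_essential = 10, m_samples = 8,
                          seed = 5)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed differs somewhere
  generate_bundle(synthetic_config(n_nodes = 80, n_essential = 10,
                                   m_samples = 8, seed = 6), d2)
  expect_false(identical(readLines(file.path(d1, "ppi.tsv")),
                         readLines(file.path(d2, "ppi.tsv"))))
})

test_that("generated files parse cleanly through the pipeline readers", {
  cfg <- synthetic_config(n_nodes = 100, n_essential = 12, m_samples = 10,
                          seed = 11)
  d <- tempfile()
  generate_bundle(cfg, d)
  edges <- read_ppi_edgelist(file.path(d, "ppi.tsv"))
  expr <- suppressMessages(read_expression(file.path(d, "expression.tsv")))
  dag <- read_go_obo(file.path(d, "go.obo"))
  ann <- read_gaf(file.path(d, "annotations.gaf"))
  orth <- read_orthology(file.path(d, "orthology.tsv"))
  gold <- read_gold_list(file.path(d, "essential.txt"))
  expect_equal(nrow(expr), 100)
  expect_equal(ncol(expr), 10)
  expect_length(gold, 12)
  expect_equal(orth$N, cfg$n_species)
  # building the weighted PIN raises no warnings at default policies
  expect_no_warning(pin <- build_weighted_pin(edges, expr, ann, dag))
  expect_setequal(pin$nodes, rownames(expr))
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(manifest$config$seed, 11)
})

test_that("rho = 1 modules are perfectly co-expressed after parsing", {
  cfg <- synthetic_config(n_nodes = 60, n_essential = 8, m_samples = 6,
                          rho = 1, seed = 3)
  b <- generate_bundle(cfg, tempfile())$bundle
  d <- tempfile(); generate_bundle(cfg, d)
  expr <- suppressMessages(read_expression(file.path(d, "expression.tsv")))
  mods <- split(b$ids, b$module)
  mods <- mods[names(mods) != "0"]
  checked <- 0L
  for (mem in mods) {
    if (length(mem) < 2) next
    pr <- compute_pcc(expr[mem[[1]], ], expr[mem[[2]], ])
    expect_equal(pr, 1, tolerance = 1e-6)   # 6-decimal file rounding
    checked <- checked + 1L
  }
  expect_gt(checked, 0)
})

test_that("planted essentials gain weighted degree and orthologous score", {
  cfg <- synthetic_config(n_nodes = 150, n_essential = 15, m_samples = 12,
                          seed = 21)
  b <- generate_bundle(cfg, tempfile())$bundle
  pin <- suppressMessages(
    build_weighted_pin(b$edges, b$expression, b$annotations, b$dag))
  wd <- weighted_degree(pin)
  ess <- b$essential
  bg <- setdiff(pin$nodes, ess)
  expect_gt(mean(wd[ess]), mean(wd[bg]))
  # orthology separation: IS_OS rank-orders essential vs background, AUC > 0.9
  os <- b$orthology$n[pin$nodes] / b$orthology$N
  lab <- pin$nodes %in% ess
  auc <- mean(outer(os[lab], os[!lab], ">") +
                0.5 * outer(os[lab], os[!lab], "=="))
  expect_gt(auc, 0.9)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_nodes = 10, n_essential = 2, pa_m = 20),
               "simple-graph")
  expect_error(synthetic_config(n_nodes = 10, n_essential = 10), "n_essential")
  expect_error(synthetic_config(dag_depth = 1, dag_branching = 2,
                                n_essential = 10), "fewer leaves")
  expect_error(synthetic_config(rho = 1.5), "rho")
})

test_that("the toy worked example reproduces hand-computed values", {
  toy <- generate_toy_example()
  pin <- toy$pin
  w <- function(a, b) pin$edges$weight[pin$edges$u == a & pin$edges$v == b]
  expect_equal(w("A", "B"), 1)                       # sim 1, pcc 1
  expect_equal(w("A", "C"), 0)                       # pcc -1 clamped
  # Sim(GO:4 vs GO:3) = 1.44/4.24 = 18/53; PCC(A,D) = 3/sqrt(10)
  expect_equal(w("A", "D"), (18 / 53) * (3 / sqrt(10)), tolerance = 1e-12)
  expect_equal(w("B", "E"), 1 * 0.8)                 # same term, pcc 0.8
  expect_equal(w("D", "F"), 0)                       # F zero-variance
  st <- init_influence(pin, toy$orthology, imepp_params(lambda = 0.2))
  i <- function(id) match(id, st$ids)
  expect_equal(st$max_inf_topo, 1.8)                 # B: 1 + 0.8
  expect_equal(st$is_topo[[i("B")]], 1)
  expect_equal(st$is_os[[i("F")]], 1)                # n_u = 10 of N = 10
  expect_equal(st$is[[i("B")]], 0.2 * 0.1 + 0.8 * 1)
  # golden k = 3 selection trace (hand-verified: B first; discounting B's
  # neighbors drops A below F's pure-orthology score at iteration 3)
  trace <- select_seeds(pin, st, 3)
  expect_identical(trace$protein, c("B", "A", "F"))
  expect_equal(trace$score[[1]], 0.82)
  expect_equal(trace$score[[2]],
               0.2 * 0.9 + 0.8 * ((1.3221943 - 1 - (1.3221943 - 1) * 0.001) / 1.8),
               tolerance = 1e-6)
  # lambda endpoints disagree on the first pick by construction
  st0 <- init_influence(pin, toy$orthology, imepp_params(lambda = 0))
  st1 <- init_influence(pin, toy$orthology, imepp_params(lambda = 1))
  expect_identical(select_seeds(pin, st0, 1)$protein, "B")  # top weighted degree
  expect_identical(select_seeds(pin, st1, 1)$protein, "F")  # top orthology
})
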