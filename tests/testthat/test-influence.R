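star_pin <- function(w = c(1, 1, 1)) {
  weighted_pin(data.frame(u = "HUB", v = c("L1", "L2", "L3"), weight = w))
}

test_that("init_influence normalizes topology and orthology as specified", {
  pin <- star_pin()
  orth <- orthology(c(HUB = 2, L1 = 4, L2 = 1, L3 = 0), N = 4)
  st <- init_influence(pin, orth, imepp_params(lambda = 0.2))
  i <- function(id) match(id, st$ids)
  expect_equal(st$inf_topo[[i("HUB")]], 3)
  expect_equal(st$is_topo[[i("HUB")]], 1)
  expect_equal(st$is_topo[[i("L1")]], 1 / 3)
  expect_equal(st$max_inf_topo, 3)
  expect_equal(st$is_os[[i("L1")]], 1)       # OS normalized by max OS
  expect_equal(st$is_os[[i("HUB")]], 0.5)
  expect_equal(max(st$is_topo), 1)
  expect_equal(max(st$is_os), 1)
  expect_true(all(st$t == 0) && all(st$tt == 0) && !any(st$seed))
})

test_that("lambda endpoints and the blend formula hold", {
  pin <- star_pin()
  orth <- orthology(c(HUB = 1, L1 = 2, L2 = 0, L3 = 0), N = 2)
  st0 <- init_influence(pin, orth, imepp_params(lambda = 0))
  expect_equal(st0$is, st0$is_topo)
  st1 <- init_influence(pin, orth, imepp_params(lambda = 1))
  expect_equal(st1$is, st1$is_os)
  # direct substitution: lambda 0.2, IS_OS 0.5, IS_topo 1 -> 0.9
  st <- init_influence(pin, orth, imepp_params(lambda = 0.2))
  i_hub <- match("HUB", st$ids)
  expect_equal(st$is_os[[i_hub]], 0.5)
  expect_equal(st$is_topo[[i_hub]], 1)
  expect_equal(st$is[[i_hub]], 0.2 * 0.5 + 0.8 * 1)
})

test_that("degenerate normalizers raise the documented errors", {
  flat <- weighted_pin(data.frame(u = "A", v = "B", weight = 0))
  orth_ok <- orthology(c(A = 1, B = 0), N = 2)
  expect_error(init_influence(flat, orth_ok, imepp_params(lambda = 0.5)),
               "topology is uninformative")
  # lambda = 1 ignores the flat topology
  expect_silent(st <- init_influence(flat, orth_ok, imepp_params(lambda = 1)))
  expect_equal(st$is, st$is_os)
  pin <- star_pin()
  orth_zero <- orthology(c(HUB = 0, L1 = 0, L2 = 0, L3 = 0), N = 2)
  expect_error(init_influence(pin, orth_zero, imepp_params(lambda = 0.5)),
               "orthology is uninformative")
  expect_silent(init_influence(pin, orth_zero, imepp_params(lambda = 0)))
  # proteins absent from the table get n_u = 0
  part <- orthology(c(HUB = 2), N = 4)
  st <- init_influence(pin, part, imepp_params(lambda = 0.2))
  expect_equal(st$is_os[match("L1", st$ids)], 0)
})

test_that("influence_discount matches the worked examples and the exact form", {
  pin <- weighted_pin(data.frame(u = "V", v = c("S1", "S2", "X"),
                                 weight = c(2, 2, 6)))
  orth <- orthology(stats::setNames(c(1, 1, 1, 1), pin$nodes), N = 2)
  st <- init_influence(pin, orth, imepp_params(lambda = 0, p = 0.001))
  iv <- match("V", st$ids)
  # no seed neighbors: ID = Inf_topo * p
  expect_equal(influence_discount("V", st), 10 * 0.001)
  # two seed neighbors, tt = 4: (6 - 6 * 2 * 0.001) * 0.001
  st$t[[iv]] <- 2L; st$tt[[iv]] <- 4
  expect_equal(influence_discount("V", st), 0.005988)
  exact <- exact_discount(10, 4, 2, 0.001)          # 0.998001 * 0.006
  expect_equal(exact, 0.005988006, tolerance = 1e-10)
  expect_lte(abs(influence_discount("V", st) - exact),
             (2 * 0.001)^2 * 6 * 0.001)
  # seeds cannot be discounted
  st$seed[[iv]] <- TRUE
  expect_error(influence_discount("V", st), "already a seed")
  expect_error(influence_discount("Z", st), "unknown protein")
})

test_that("discount is floored at 0 when t*p >= 1, with a message", {
  pin <- star_pin()
  orth <- orthology(c(HUB = 1, L1 = 1, L2 = 1, L3 = 1), N = 2)
  st <- init_influence(pin, orth, imepp_params(lambda = 0, p = 0.9))
  ih <- match("HUB", st$ids)
  st$t[[ih]] <- 3L; st$tt[[ih]] <- 1
  expect_message(val <- influence_discount("HUB", st), "floored")
  expect_identical(val, 0)
})

test_that("discount decreases weakly along random seed-update sequences", {
  set.seed(67)
  for (rep in 1:20) {
    inf <- runif(1, 1, 20)
    p <- 0.001
    t <- 0L; tt <- 0
    prev <- imepp:::id_discount(inf, tt, t, p)
    for (step in 1:15) {
      t <- t + 1L
      tt <- min(tt + runif(1, 0, inf / 20), inf)
      cur <- imepp:::id_discount(inf, tt, t, p)
      expect_lte(cur, prev + 1e-15)
      prev <- cur
    }
  }
})

test_that("update_after_seed is local and matches a from-scratch recompute", {
  set.seed(31)
  pin <- random_pin(12)
  orth <- random_orthology(pin$nodes)
  st <- init_influence(pin, orth, imepp_params(lambda = 0.3, p = 0.001))
  init_is_topo <- st$is_topo
  seeds <- character(0)
  for (step in 1:5) {
    cand <- which(!st$seed)
    s <- cand[which.max(st$is[cand])]
    st$seed[[s]] <- TRUE
    seeds <- c(seeds, st$ids[[s]])
    nbrs <- pin$adj[[s]]$idx
    before <- st
    st <- update_after_seed(st$ids[[s]], pin, st)
    untouched <- setdiff(seq_along(st$ids), nbrs)
    expect_identical(st$is[untouched], before$is[untouched])
    expect_identical(st$t[untouched], before$t[untouched])
    # invariants: tt bounded by weighted degree, t by degree
    expect_true(all(st$tt <= st$inf_topo + 1e-12))
    expect_true(all(st$t <= unname(node_degree(pin))))
    # IS blend identity for non-seeds
    ns <- which(!st$seed)
    expect_equal(st$is[ns],
                 st$lambda * st$is_os[ns] + (1 - st$lambda) * st$is_topo[ns])
    # discounted scores never exceed their initial value
    expect_true(all(st$is_topo[ns] <= init_is_topo[ns] + 1e-12))
    # from-scratch recompute of every IS from the accumulated (t, tt)
    for (v in ns) {
      expected_topo <- if (st$t[[v]] == 0L) {
        st$inf_topo[[v]] / st$max_inf_topo
      } else {
        (imepp:::id_discount(st$inf_topo[[v]], st$tt[[v]], st$t[[v]], st$p) /
           st$p) / st$max_inf_topo
      }
      expect_identical(st$is_topo[[v]], expected_topo)
    }
  }
  # weight-0 edge: t increments, tt unchanged, IS_topo scaled by (1 - t*p)
  pin0 <- weighted_pin(data.frame(u = c("A", "A"), v = c("B", "C"),
                                  weight = c(0, 5)))
  orth0 <- orthology(c(A = 1, B = 1, C = 1), N = 2)
  st0 <- init_influence(pin0, orth0, imepp_params(lambda = 0, p = 0.001))
  ib <- match("B", st0$ids)
  st0$seed[[ib]] <- TRUE
  st1 <- update_after_seed("B", pin0, st0)
  ia <- match("A", st1$ids)
  expect_equal(st1$t[[ia]], 1L)
  expect_equal(st1$tt[[ia]], 0)
  expect_equal(st1$is_topo[[ia]], st0$is_topo[[ia]] * (1 - 1 * 0.001))
  expect_error(update_after_seed("C", pin0, st0), "not been marked")
})
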