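test_that("empty systems reduce to trivial compositions", {
  lp <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 700 * 8.7e5,
                       n_dna_sites = 2)
  # no DNA, no zinc: all protein sits in the apo state
  st <- solve_state(lp, mixture_totals(1e-6, 0, 0))
  expect_equal(st$L_free, 0)
  expect_equal(as.numeric(st$p_free[1]), 1e-6)
  expect_equal(sum(st$p_free[-1]), 0)
  expect_equal(sum(st$d_complex), 0)

  # zero zinc with DNA present: only K_0 is active
  st0 <- solve_state(lp, mixture_totals(1e-6, 1e-7, 0))
  s_expected <- lp$K_dna[["K_0"]] * st0$p_free[["p_0"]]
  expect_equal(st0$site_occupancy, s_expected / (1 + s_expected),
               tolerance = 1e-12)

  # all-zero DNA affinities leave DNA free
  lp0 <- linkage_params(K_Zn = 2.3e13, n_dna_sites = 2,
                        K_dna = rep(0, 7))
  stz <- solve_state(lp0, mixture_totals(1e-6, 1e-7, 5e-6))
  expect_equal(as.numeric(stz$d_complex[["d_0"]]), 1e-7)
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(linkage_params(K_Zn = -1, K_4 = 1, K_6 = 2, n_dna_sites = 2))
  expect_error(linkage_params(K_Zn = 1e13, K_4 = 1e6, K_6 = 1e5,
                              n_dna_sites = 2),
               "non-decreasing")
  expect_error(linkage_params(K_Zn = 1e13, K_4 = 1e6, K_6 = 1e9,
                              n_dna_sites = 5))
  expect_error(mixture_totals(-1e-9, 0, 0))
})

test_that("binomial zinc-state weights satisfy the algebraic self-check", {
  lp <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 6.1e8,
                       n_dna_sites = 2)
  for (L in c(1e-15, 1e-12, 1e-9, 1e-6)) {
    st <- solve_state(lp, mixture_totals(1e-6, 0, L,
                                         zinc_mode = "free_clamped"))
    x <- lp$K_Zn * L
    expect_equal(sum(st$p_free) / st$p_free[["p_0"]], (1 + x)^6,
                 tolerance = 1e-12)
  }
})

test_that("oligomeric complexes dominate at EMSA conditions (high zinc)", {
  # znuA: two dimer-sites, K_6 = 700 K_4 -> 2:1 complex predominant
  znua <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 700 * 8.7e5,
                         n_dna_sites = 2)
  st2 <- solve_state(znua, mixture_totals(200e-9, 65e-9, 5e-6))
  expect_gte(st2$d_complex[["d_2"]] / 65e-9, 0.95)

  # zitB: three dimer-sites, K_6 = 4000 K_4 -> 3:1 complex predominant
  zitb <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                         n_dna_sites = 3)
  st3 <- solve_state(zitb, mixture_totals(200e-9, 65e-9, 5e-6))
  expect_gte(st3$d_complex[["d_3"]] / 65e-9, 0.95)
})

test_that("solver agrees with the nested-bisection oracle on random systems", {
  set.seed(42)
  for (k in 1:100) {
    cs <- random_linkage_case()
    st <- solve_state(cs$params, cs$totals)
    or <- oracle_solve_state(cs$params, cs$totals)
    expect_lt(rel_diff(st$L_free, or$L_free), 1e-8)
    expect_lt(max(rel_diff(as.numeric(st$p_free), or$p_free)), 1e-8)
    expect_lt(max(rel_diff(as.numeric(st$d_complex), or$d_complex)), 1e-8)
  }
})

test_that("conservation laws hold at every returned state", {
  set.seed(99)
  for (k in 1:25) {
    cs <- random_linkage_case()
    st <- solve_state(cs$params, cs$totals)
    expect_lt(rel_diff(sum(st$d_complex), cs$totals$D_total), 1e-10)
    P_acc <- sum(st$p_free) + sum(st$bound_by_state)
    expect_lt(rel_diff(P_acc, cs$totals$P_total), 1e-8)
    L_acc <- st$L_free + sum((0:6) * st$p_free) +
      sum((0:6) * st$bound_by_state)
    expect_lt(rel_diff(L_acc, cs$totals$L_value), 1e-8)
  }
})

test_that("detailed balance holds among DNA-bound zinc states", {
  set.seed(7)
  for (k in 1:20) {
    cs <- random_linkage_case()
    st <- solve_state(cs$params, cs$totals)
    K <- as.numeric(cs$params$K_dna)
    p <- as.numeric(st$p_free)
    b <- as.numeric(st$bound_by_state)
    ok <- which(p > 0 & K > 0 & b > 0)
    if (length(ok) >= 2) {
      i <- ok[1]
      for (j in ok[-1]) {
        lhs <- (b[j] / p[j]) / (b[i] / p[i])
        expect_lt(rel_diff(lhs, K[j] / K[i]), 1e-6)
      }
    }
  }
})

test_that("occupancy is monotone in total zinc and total protein", {
  lp <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                       n_dna_sites = 3)
  zgrid <- seq(0, 5e-6, length.out = 26)
  prof <- zinc_titration_profile(lp, 200e-9, 65e-9, zgrid)
  expect_true(all(diff(prof$frac_3to1) >= -1e-12))
  th <- vapply(zgrid, function(L)
    solve_state(lp, mixture_totals(200e-9, 65e-9, L))$site_occupancy,
    numeric(1))
  expect_true(all(diff(th) >= -1e-12))
  # in protein: at fixed *free* zinc (buffered), more dimer always binds
  # more. (At fixed total zinc this can reverse: extra protein dilutes
  # the zinc pool over more sites and lowers the active fraction.)
  pgrid <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5) * 1e-6
  occ <- vapply(pgrid, function(P)
    solve_state(lp, mixture_totals(P, 65e-9, 1e-13,
                                   zinc_mode = "free_clamped"))$site_occupancy,
    numeric(1))
  expect_true(all(diff(occ) >= -1e-12))
})

test_that("zinc saturation drives the dimer population into the 6-bound state", {
  lp <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 6.1e8,
                       n_dna_sites = 2)
  P <- 1e-6
  st <- solve_state(lp, mixture_totals(P, 0, 100 * 6 * P))
  expect_gte(st$p_free[["p_6"]] / sum(st$p_free), 0.999)
})

test_that("zinc titration profiles are normalized and shaped as expected", {
  # equal K_6 = K_4 on znuA: no significant oligomeric binding
  flat <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 8.7e5,
                         n_dna_sites = 2)
  zgrid <- seq(0, 5e-6, length.out = 26)
  prof <- zinc_titration_profile(flat, 200e-9, 65e-9, zgrid)
  expect_true(all(abs(rowSums(prof[-1]) - 1) < 1e-10))
  expect_lt(max(prof$frac_2to1), 0.05)

  # K_6 = 4000 K_4 on zitB: 3:1 reaches 95% at the top of the zinc range
  zitb <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                         n_dna_sites = 3)
  prof3 <- zinc_titration_profile(zitb, 200e-9, 65e-9, zgrid)
  expect_gte(prof3$frac_3to1[nrow(prof3)], 0.95)

  # zero-zinc grid point equals the zinc-free equilibrium
  st0 <- solve_state(flat, mixture_totals(200e-9, 65e-9, 0))
  expect_equal(as.numeric(prof[1, -1]),
               as.numeric(st0$d_complex) / 65e-9, tolerance = 1e-10)
})

test_that("protein titration co-titrates zinc and fills sites oligomerically", {
  zitb <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                         n_dna_sites = 3)
  prof <- protein_titration_profile(zitb, 3e-6, 4.0,
                                    seq(0, 6, length.out = 25))
  expect_true(all(abs(rowSums(prof[-1]) - 1) < 1e-10))
  expect_equal(prof$frac_free[1], 1)
  expect_true(all(diff(prof$frac_3to1) >= -1e-12))
  last <- nrow(prof)
  expect_gt(prof$frac_3to1[last], prof$frac_1to1[last])

  # all-zero DNA affinities: DNA stays free along the whole titration
  lp0 <- linkage_params(K_Zn = 2.3e13, n_dna_sites = 3, K_dna = rep(0, 7))
  prof0 <- protein_titration_profile(lp0, 3e-6, 4.0, c(0, 1, 3, 6))
  expect_true(all(prof0$frac_free == 1))
})
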