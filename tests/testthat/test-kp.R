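human_params <- function(k_kmo = 22) {
  kp_params(k_tdo_ido = 1, k_kat1 = 2.08, k_kynu1 = 0.46, k_kmo = k_kmo,
            k_kat2 = 1, k_kynu2 = 1, k_3hao = 1, k_clear = 1)
}

test_that("the ODE right-hand side reflects the pathway topology", {
  p <- human_params()
  st <- c(Trp = 1, KYN = 0, HK = 0, KA = 0, AA = 0, XA = 0, HAA = 0, QUIN = 0)
  d <- kp_rhs(st, p)
  expect_equal(d[["Trp"]], 0)             # clamped
  expect_gt(d[["KYN"]], 0)
  expect_equal(unname(d[c("HK", "KA", "AA", "XA", "HAA", "QUIN")]),
               rep(0, 6))
  expect_error(kp_rhs(replace(st, 2, -1), p), "negative")

  # derivatives vanish at the analytic steady state
  ss <- analytic_steady_state(p, 1)
  expect_lt(max(abs(kp_rhs(ss$state, p))), 1e-10)

  # doubling all constants doubles all derivatives (time rescaling)
  st2 <- ss$state * 0.7
  p2 <- kp_params(k_tdo_ido = 2, k_kat1 = 4.16, k_kynu1 = 0.92, k_kmo = 44,
                  k_kat2 = 2, k_kynu2 = 2, k_3hao = 2, k_clear = 2)
  expect_equal(kp_rhs(st2, p2), 2 * kp_rhs(st2, p), tolerance = 1e-12)
})

test_that("analytic steady states match the closed-form constants", {
  p <- human_params()
  ss <- analytic_steady_state(p, 1)$state
  expect_equal(ss[["KYN"]], 1 / 24.54, tolerance = 1e-12)
  expect_equal(ss[["HK"]], 22 / (24.54 * 2), tolerance = 1e-12)

  # removing the KMO branch empties HK and shortens the KYN denominator
  p0 <- kp_params(k_tdo_ido = 1, k_kat1 = 2.08, k_kynu1 = 0.46, k_kmo = 0)
  ss0 <- analytic_steady_state(p0, 1)$state
  expect_equal(ss0[["HK"]], 0)
  expect_equal(ss0[["KYN"]], 1 / (2.08 + 0.46), tolerance = 1e-12)

  # first-order homogeneity: doubling Trp doubles every level
  ss2 <- analytic_steady_state(p, 2)$state
  expect_equal(unname(ss2), unname(2 * ss), tolerance = 1e-12)

  expect_error(analytic_steady_state(kp_params(k_clear = 0), 1), "clearance")
})

test_that("numeric integration agrees with the analytic solution", {
  set.seed(8)
  for (r in 1:12) {
    p <- kp_params(k_tdo_ido = runif(1, 0.1, 5), k_kat1 = runif(1, 0.1, 5),
                   k_kynu1 = runif(1, 0.1, 5), k_kmo = runif(1, 0.1, 30),
                   k_kat2 = runif(1, 0.1, 5), k_kynu2 = runif(1, 0.1, 5),
                   k_3hao = runif(1, 0.1, 5), k_clear = runif(1, 0.1, 5))
    trp <- runif(1, 0.01, 2)
    a <- analytic_steady_state(p, trp)$state
    b <- integrate_to_steady_state(p, trp, tol = 1e-10)$state
    expect_lt(max(abs(a - b) / pmax(a, 1e-12)), 1e-6)
  }
  # starting at the steady state returns immediately
  p <- human_params()
  a <- analytic_steady_state(p, 1)
  out <- integrate_to_steady_state(p, 1, state0 = a$state, tol = 1e-8)
  expect_equal(out$state, a$state, tolerance = 1e-12)
  # zero Trp drains everything
  expect_equal(max(integrate_to_steady_state(p, 0)$state), 0)
})

test_that("steady-state fluxes balance and partition by rate constants", {
  p <- human_params()
  ss <- analytic_steady_state(p, 1)$state
  # mass balance for the non-terminal species
  expect_equal(p$k_tdo_ido * ss[["Trp"]],
               (p$k_kat1 + p$k_kynu1 + p$k_kmo) * ss[["KYN"]],
               tolerance = 1e-10)
  expect_equal(p$k_kmo * ss[["KYN"]],
               (p$k_kat2 + p$k_kynu2) * ss[["HK"]], tolerance = 1e-10)
  # KA:AA:HK production fluxes proportional to k_kat1:k_kynu1:k_kmo
  flux <- c(p$k_kat1, p$k_kynu1, p$k_kmo) * ss[["KYN"]]
  expect_equal(flux / flux[1],
               c(p$k_kat1, p$k_kynu1, p$k_kmo) / p$k_kat1, tolerance = 1e-12)

  # increasing k_kmo lowers KYN, KA, AA and raises flux into HK
  hi <- analytic_steady_state(human_params(k_kmo = 44), 1)$state
  expect_lt(hi[["KYN"]], ss[["KYN"]])
  expect_lt(hi[["KA"]], ss[["KA"]])
  expect_lt(hi[["AA"]], ss[["AA"]])
  expect_gt(44 * hi[["KYN"]], 22 * ss[["KYN"]])
})

test_that("HK is buffered against k_kmo while KYN is not", {
  eq <- hk_equivalence_check(human_params(22), human_params(44))
  expect_equal(eq$hk_rel_diff, 0.0546, tolerance = 0.01)
  expect_equal(eq$kyn_rel_diff, 0.4727, tolerance = 0.01)
  expect_true(eq$equivalence_holds)
  expect_equal(eq$sensitivity_g, 2.54 / 24.54, tolerance = 1e-12)

  # k_kmo >> k_kynu1 + k_kat1: HK invariant under doubling
  big <- hk_equivalence_check(human_params(1e6), human_params(2e6))
  expect_lt(big$hk_rel_diff, 1e-4)

  # opposite limit: HK scales almost linearly with k_kmo
  small <- hk_equivalence_check(human_params(0.01), human_params(0.02))
  expect_equal(small$hk_rel_diff, 1, tolerance = 0.01)

  expect_error(
    hk_equivalence_check(human_params(22),
                         kp_params(k_tdo_ido = 2, k_kmo = 44)),
    "only in k_kmo")
})

test_that("Wilcoxon comparison uses the exact small-sample distribution", {
  # completely separated 8 vs 8: two-sided exact P = 2 / choose(16, 8)
  d <- tibble::tibble(genotype = rep(c("AA", "GG"), each = 8),
                      KYN = c(1:8, 101:108))
  w <- group_compare_wilcoxon(d, "KYN", "genotype")
  expect_equal(w$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(w$method, "exact")

  # identical (permuted) groups are non-significant
  set.seed(9)
  v <- rnorm(16)
  d2 <- tibble::tibble(genotype = rep(c("AA", "GG"), each = 8),
                       KYN = c(v[1:8], sample(v[1:8])))
  w2 <- group_compare_wilcoxon(
    tibble::tibble(genotype = d2$genotype, KYN = c(v[1:8], v[8:1])), "KYN",
    "genotype")
  expect_gt(w2$p_value, 0.9)

  # all values tied across groups
  d3 <- tibble::tibble(genotype = rep(c("AA", "GG"), each = 4), KYN = 1)
  w3 <- group_compare_wilcoxon(d3, "KYN", "genotype")
  expect_equal(w3$p_value, 1)
  expect_equal(w3$flag, "all values tied")
})

test_that("the simulated nutrigenetic cohort reproduces the genotype contrast", {
  par2 <- list(AA = human_params(22), GG = human_params(44))
  # no noise: concentrations are exactly the analytic steady states
  kp0 <- simulate_kp_cohort(2, par2, trp_levels = c(0.04, 0.08),
                            noise_cv = 0, seed = 1)
  ssAA <- analytic_steady_state(par2$AA, 0.04)$state
  row <- dplyr::filter(kp0, genotype == "AA", timepoint == "basal")[1, ]
  expect_equal(unlist(row[names(ssAA)]), ssAA, tolerance = 1e-12)

  # identical k_kmo: the two groups are exchangeable
  same <- simulate_kp_cohort(4, list(A = human_params(), B = human_params()),
                             noise_cv = 0, seed = 2)
  a <- dplyr::filter(same, genotype == "A", timepoint == "basal")
  b <- dplyr::filter(same, genotype == "B", timepoint == "basal")
  expect_equal(a$HK, b$HK)
  expect_equal(a$KYN, b$KYN)

  # k_kmo ratio 2, cv 0.1, 8 vs 8: KYN separates, HK does not (mostly)
  kyn_sig <- hk_sig <- logical(25)
  for (r in 1:25) {
    co <- simulate_kp_cohort(8, par2, noise_cv = 0.1, seed = 100 + r)
    basal <- dplyr::filter(co, timepoint == "basal")
    kyn_sig[r] <- group_compare_wilcoxon(basal, "KYN", "genotype")$p_value < 0.05
    hk_sig[r] <- group_compare_wilcoxon(basal, "HK", "genotype")$p_value < 0.05
  }
  expect_gte(mean(kyn_sig), 0.9)
  expect_lt(mean(hk_sig), 0.5)

  expect_error(simulate_kp_cohort(2, par2, trp_levels = c(0, 1)), "positive")
})
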