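# First-order kinetic model of the kynurenine pathway (KP).
#
# Topology (tryptophan catabolism):
#   Trp -> KYN            (k_tdo_ido; TDO/IDO)
#   KYN -> KA             (k_kat1)    KYN -> AA (k_kynu1)   KYN -> HK (k_kmo)
#   HK  -> XA             (k_kat2)    HK  -> HAA (k_kynu2)
#   HAA -> QUIN           (k_3hao)
#   KA, AA, XA, QUIN cleared at first order (k_clear) so steady states exist.
# Trp is a clamped boundary condition (diet-driven); all enzymes operate in
# their first-order regime ([S] << K_M), so each rate constant k = kcat/K_M
# folded with the enzyme level.

kp_species <- c("Trp", "KYN", "HK", "KA", "AA", "XA", "HAA", "QUIN")

#' Kynurenine-pathway rate constants
#'
#' First-order rate constants (s^-1 mM^-1 scale when derived from
#' kcat/K_M and enzyme level). Defaults use the human-derived constants for
#' the three kynurenine-consuming enzymes (k_kmo = 22, k_kynu1 = 0.46,
#' k_kat1 = 2.08); constants not reported are set to 1, which is
#' inconsequential for the concentration ratios and genotype contrasts the
#' model is used for (only ratios of constants enter the steady states).
#'
#' @param k_tdo_ido Trp -> KYN.
#' @param k_kat1 KYN -> kynurenic acid (KA).
#' @param k_kynu1 KYN -> anthranilic acid (AA).
#' @param k_kmo KYN -> 3-hydroxykynurenine (HK).
#' @param k_kat2 HK -> xanthurenic acid (XA).
#' @param k_kynu2 HK -> 3-hydroxyanthranilic acid (HAA).
#' @param k_3hao HAA -> quinolinic acid (QUIN).
#' @param k_clear Clearance of the terminal species KA, AA, XA, QUIN
#'   (single shared constant, or a named vector over those species).
#' @return A `kp_params` list.
#' @export
kp_params <- function(k_tdo_ido = 1, k_kat1 = 2.08, k_kynu1 = 0.46,
                      k_kmo = 22, k_kat2 = 1, k_kynu2 = 1, k_3hao = 1,
                      k_clear = 1) {
  terminals <- c("KA", "AA", "XA", "QUIN")
  if (length(k_clear) == 1 && is.null(names(k_clear))) {
    k_clear <- setNames(rep(k_clear, 4), terminals)
  }
  if (!all(terminals %in% names(k_clear))) {
    abort("k_clear must be a scalar or named over KA, AA, XA, QUIN")
  }
  p <- list(k_tdo_ido = k_tdo_ido, k_kat1 = k_kat1, k_kynu1 = k_kynu1,
            k_kmo = k_kmo, k_kat2 = k_kat2, k_kynu2 = k_kynu2,
            k_3hao = k_3hao, k_clear = k_clear[terminals])
  if (any(unlist(p) < 0)) abort("rate constants must be non-negative")
  structure(p, class = "kp_params")
}

#' Time derivatives of the KP model
#'
#' Right-hand side of the ODE system; Trp is clamped (derivative 0).
#'
#' @param state Named numeric vector over
#'   `c("Trp","KYN","HK","KA","AA","XA","HAA","QUIN")` (mM).
#' @param params [kp_params()].
#' @return Named derivative vector (mM per time unit).
#' @export
kp_rhs <- function(state, params) {
  if (any(state < 0)) abort("negative concentrations are not allowed")
  s <- state[kp_species]
  kc <- params$k_clear
  d <- c(
    Trp = 0,
    KYN = params$k_tdo_ido * s[["Trp"]] -
      (params$k_kat1 + params$k_kynu1 + params$k_kmo) * s[["KYN"]],
    HK = params$k_kmo * s[["KYN"]] -
      (params$k_kat2 + params$k_kynu2) * s[["HK"]],
    KA = params$k_kat1 * s[["KYN"]] - kc[["KA"]] * s[["KA"]],
    AA = params$k_kynu1 * s[["KYN"]] - kc[["AA"]] * s[["AA"]],
    XA = params$k_kat2 * s[["HK"]] - kc[["XA"]] * s[["XA"]],
    HAA = params$k_kynu2 * s[["HK"]] - params$k_3hao * s[["HAA"]],
    QUIN = params$k_3hao * s[["HAA"]] - kc[["QUIN"]] * s[["QUIN"]]
  )
  d[kp_species]
}

#' Analytic steady state of the KP model
#'
#' Mass balance of the first-order network gives, with Trp clamped:
#' `KYNss = k_tdo_ido * Trp / (k_kat1 + k_kynu1 + k_kmo)`,
#' `HKss = k_kmo * KYNss / (k_kat2 + k_kynu2)`,
#' `HAAss = k_kynu2 * HKss / k_3hao`, and production/clearance for the
#' terminal species. All levels are proportional to Trp (first-order
#' homogeneity).
#'
#' @param params [kp_params()].
#' @param trp Clamped tryptophan concentration (mM, >= 0).
#' @return A `kp_steady_state` object: list with `state` (named vector),
#'   `residual` (max |d/dt| at the state), `method = "analytic"`, `params`,
#'   `trp`.
#' @export
analytic_steady_state <- function(params, trp) {
  if (trp < 0) abort("Trp must be non-negative")
  cons_kyn <- params$k_kat1 + params$k_kynu1 + params$k_kmo
  cons_hk <- params$k_kat2 + params$k_kynu2
  if (cons_kyn <= 0 && params$k_tdo_ido > 0 && trp > 0) {
    abort("KYN has influx but no consumption; no steady state")
  }
  kyn <- if (cons_kyn > 0) params$k_tdo_ido * trp / cons_kyn else 0
  hk <- if (params$k_kmo == 0) 0 else {
    if (cons_hk <= 0) abort("HK has influx but no consumption; no steady state")
    params$k_kmo * kyn / cons_hk
  }
  haa <- if (params$k_kynu2 == 0) 0 else {
    if (params$k_3hao <= 0) abort("HAA has influx but no consumption; no steady state")
    params$k_kynu2 * hk / params$k_3hao
  }
  kc <- params$k_clear
  term <- function(prod, key) {
    if (prod == 0) return(0)
    if (kc[[key]] <= 0) abort(paste0(key, " has influx but no clearance; no steady state"))
    prod / kc[[key]]
  }
  st <- c(Trp = trp, KYN = unname(kyn), HK = unname(hk),
          KA = term(params$k_kat1 * kyn, "KA"),
          AA = term(params$k_kynu1 * kyn, "AA"),
          XA = term(params$k_kat2 * hk, "XA"),
          HAA = unname(haa),
          QUIN = term(params$k_3hao * haa, "QUIN"))
  structure(list(state = st, residual = max(abs(kp_rhs(st, params))),
                 method = "analytic", params = params, trp = trp),
            class = "kp_steady_state")
}

#' @export
print.kp_steady_state <- function(x, ...) {
  cat("<kp_steady_state> (", x$method, ") max |d/dt| = ",
      format(x$residual), "\n", sep = "")
  print(round(x$state, 6))
  invisible(x)
}

#' Integrate the KP model to steady state
#'
#' Stiff-safe numerical integration (lsoda) in doubling time chunks until
#' the largest derivative magnitude falls below `tol`; the independent
#' numerical check of [analytic_steady_state()].
#'
#' @param params [kp_params()].
#' @param trp Clamped Trp level (mM).
#' @param state0 Optional named start state (default: all zero except Trp).
#' @param tol Convergence tolerance on max |d/dt| (default 1e-10).
#' @param max_time Give up beyond this integration time.
#' @return A `kp_steady_state` object with `method = "integrated"`.
#' @export
integrate_to_steady_state <- function(params, trp, state0 = NULL,
                                      tol = 1e-10, max_time = 1e8) {
  if (tol <= 0) abort("tol must be positive")
  st <- c(Trp = trp, KYN = 0, HK = 0, KA = 0, AA = 0, XA = 0, HAA = 0, QUIN = 0)
  if (!is.null(state0)) st[names(state0)] <- state0
  st["Trp"] <- trp
  if (max(abs(kp_rhs(st, params))) < tol) {
    return(structure(list(state = st, residual = max(abs(kp_rhs(st, params))),
                          method = "integrated", params = params, trp = trp),
                     class = "kp_steady_state"))
  }
  deriv <- function(t, y, p) list(kp_rhs(y, p))
  t_end <- 1
  repeat {
    sol <- deSolve::ode(y = st, times = c(0, t_end), func = deriv,
                        parms = params, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    st <- pmax(sol[nrow(sol), kp_species], 0)
    names(st) <- kp_species
    if (max(abs(kp_rhs(st, params))) < tol) break
    t_end <- t_end * 4
    if (t_end > max_time) abort("no convergence to steady state within max_time")
  }
  structure(list(state = st, residual = max(abs(kp_rhs(st, params))),
                 method = "integrated", params = params, trp = trp),
            class = "kp_steady_state")
}

#' Steady-state equivalence of HK across KMO genotypes
#'
#' For two parameter sets differing only in `k_kmo` (the two KMO genotype
#' classes), compares the steady-state HK and KYN levels. Because
#' `HKss` depends on `k_kmo` only through
#' `k_kmo / (k_kynu1 + k_kat1 + k_kmo)`, HK is nearly invariant whenever
#' `k_kmo >> k_kynu1 + k_kat1`, while KYN scales as
#' `1 / (k_kynu1 + k_kat1 + k_kmo)`. The log-sensitivity
#' `d log HKss / d log k_kmo = (k_kat1 + k_kynu1) / (k_kat1 + k_kynu1 + k_kmo)`
#' is reported for both sets.
#'
#' @param params_g,params_a [kp_params()] for the two genotypes (may differ
#'   only in `k_kmo`).
#' @param trp Trp level for the evaluation (default 1; the relative
#'   contrasts do not depend on it).
#' @param rel_tol Relative HK difference under which the equivalence is
#'   declared to hold (default 0.10).
#' @return Tibble with `hk_ss_g`, `hk_ss_a`, `hk_rel_diff`, `kyn_rel_diff`,
#'   `sensitivity_g`, `sensitivity_a`, `equivalence_holds`.
#' @export
hk_equivalence_check <- function(params_g, params_a, trp = 1, rel_tol = 0.10) {
  differ <- names(which(vapply(setdiff(names(params_g), "k_clear"), function(k) {
    !isTRUE(all.equal(params_g[[k]], params_a[[k]]))
  }, logical(1))))
  if (!isTRUE(all.equal(params_g$k_clear, params_a$k_clear))) {
    differ <- c(differ, "k_clear")
  }
  if (length(setdiff(differ, "k_kmo"))) {
    abort(paste0("parameter sets may differ only in k_kmo; also differ in: ",
                 toString(setdiff(differ, "k_kmo"))))
  }
  ss_g <- analytic_steady_state(params_g, trp)$state
  ss_a <- analytic_steady_state(params_a, trp)$state
  sens <- function(p) (p$k_kat1 + p$k_kynu1) / (p$k_kat1 + p$k_kynu1 + p$k_kmo)
  # relative changes are measured against the first (reference) genotype
  rel <- function(key) {
    abs(ss_a[[key]] - ss_g[[key]]) / max(ss_g[[key]], .Machine$double.eps)
  }
  tibble(
    hk_ss_g = ss_g[["HK"]], hk_ss_a = ss_a[["HK"]],
    hk_rel_diff = rel("HK"), kyn_rel_diff = rel("KYN"),
    sensitivity_g = sens(params_g), sensitivity_a = sens(params_a),
    equivalence_holds = rel("HK") < rel_tol
  )
}

#' Wilcoxon rank-sum comparison of cohort metabolite levels
#'
#' Two-group comparison of one metabolite: exact two-sided rank-sum P for
#' small groups (min group size <= 12 and no ties), normal approximation
#' with tie correction otherwise. With every value tied across both groups,
#' P is 1 with a flag.
#'
#' @param data Cohort tibble (e.g. from [simulate_kp_cohort()]).
#' @param metabolite Column name to compare.
#' @param group Column name of the two-level grouping (e.g. `genotype`).
#' @return One-row tibble: `metabolite`, `statistic` (rank-sum W of group
#'   1), `p_value`, `method`, `flag`.
#' @export
group_compare_wilcoxon <- function(data, metabolite, group) {
  d <- as_tibble(data)
  g <- as.factor(d[[group]])
  if (nlevels(g) != 2) abort("grouping must have exactly two levels")
  x <- d[[metabolite]][g == levels(g)[1]]
  y <- d[[metabolite]][g == levels(g)[2]]
  if (!length(x) || !length(y)) abort("both groups need at least one value")
  if (length(unique(c(x, y))) == 1) {
    return(tibble(metabolite = metabolite, statistic = NA_real_, p_value = 1,
                  method = "degenerate", flag = "all values tied"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(metabolite = metabolite, statistic = unname(wt$statistic),
         p_value = wt$p.value,
         method = if (exact) "exact" else "normal approximation",
         flag = "ok")
}
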