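# shared fixtures: reference solutes and a helper that builds a
# measurement series directly from numbers (no simulator involved)

naproxen <- solute("naproxen", "acid", 4.18)
ibuprofen <- solute("ibuprofen", "acid", 4.42)
lidocaine <- solute("lidocaine", "base", 7.92)
griseofulvin <- solute("griseofulvin", "neutral")

make_series <- function(solute, c_total, c_org, c_aq, pH = NA_real_,
                        temperature = 25, ...) {
  measurement_series(
    solute,
    data.frame(c_total = c_total, c_org = c_org, c_aq = c_aq, pH = pH,
               temperature = temperature),
    ...)
}

# a flat neutral-solute series with constant log P
flat_neutral_series <- function(logP = 1.34, n = 4) {
  c_aq <- rep(1e-4, n)
  make_series(griseofulvin, c_total = seq(1e-4, 4e-4, length.out = n),
              c_org = 10^logP * c_aq, c_aq = c_aq)
}

# independent grid-scan oracle for the biphasic equilibrium: coarse log-grid
# scan for the sign change of the mass-balance residual, then plain interval
# bisection; shares no code with solve_equilibrium
grid_scan_equilibrium <- function(solute, system, n_total,
                                  n_grid = 1e5, n_bisect = 200) {
  Ka <- 10^(-solute$pKa)
  Vo <- system$volume_org
  Va <- system$volume_aq
  c_total <- n_total / (Vo + Va)
  P_N <- 10^(log10(system$P_neutral_0) + system$conc_slope_s * c_total)
  acid <- solute$ionization_class == "acid"
  resid <- function(lH) {
    cH <- 10^lH
    ch <- if (acid) cH - 1e-14 / cH else 1e-14 / cH - cH
    cn <- if (acid) ch * cH / Ka else ch * Ka / cH
    Va * (cn + ch) + Vo * (P_N * cn + system$P_ion * ch) - n_total
  }
  grid <- seq(-14, 0, length.out = n_grid)
  r <- vapply(grid, resid, 0)
  i <- which(r[-1] * r[-length(r)] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
  }
  lH <- (lo + hi) / 2
  cH <- 10^lH
  ch <- if (acid) cH - 1e-14 / cH else 1e-14 / cH - cH
  cn <- if (acid) ch * cH / Ka else ch * Ka / cH
  list(pH = -lH,
       logD = log10((P_N * cn + system$P_ion * ch) / (cn + ch)))
}
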