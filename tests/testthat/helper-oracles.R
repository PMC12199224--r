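# Independent oracles and shared fixtures. These never call the package
# functions they are used to check.

# Brute-force isotopologue distribution: enumerate every atom-level isotope
# assignment of a molecule with n1 carbons at probability p1 and n2 carbons
# at probability p2. Exponential in n1 + n2; use only for small molecules.
enumerate_distribution <- function(n1, p1, n2, p2) {
  n <- n1 + n2
  probs <- c(rep(p1, n1), rep(p2, n2))
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(grid, 1, function(z) prod(ifelse(z == 1, probs, 1 - probs)))
  k <- rowSums(grid)
  as.numeric(tapply(pr, factor(k, levels = 0:n), sum))
}

# Sequential polynomial-product oracle: multiply per-atom generating
# polynomials ((1-p) + p z) one atom at a time. Linear in atom count;
# independent of any binomial-density shortcut.
polyprod_distribution <- function(n1, p1, n2, p2) {
  coefs <- 1
  for (p in c(rep(p1, n1), rep(p2, n2)))
    coefs <- c(coefs * (1 - p), 0) + c(0, coefs * p)
  coefs
}

# Simulated low-range calibration set over several compounds, shared by the
# cascade and acceptance tests. Cached per seed within a test run.
.sim_cache <- new.env(parent = emptyenv())

build_sim_calibrations <- function(ncarb = 2:11, seed = 21,
                                   levels = c(1.1, 1.5, 2, 2.5, 3, 4, 5)) {
  key <- paste0("s", seed, "_", paste(ncarb, collapse = "."))
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  set.seed(seed)
  registry <- data.frame(name = paste0("C", ncarb), c_compound = ncarb,
                         n_tags = 1L, mz_m0 = NA_real_,
                         rt_minutes = NA_real_, stringsAsFactors = FALSE)
  specs <- registry_specs(registry)
  curves <- list()
  natural <- numeric(0)
  for (sp in specs) {
    std <- simulate_dilution_series(sp, levels, simulation_config())
    enr <- enrichment_table(std, registry)
    curves[[sp$name]] <- fit_low_range(
      data.frame(measured = enr$apparent_atom_pct,
                 true = enr$true_atom_pct),
      compound = sp$name)
    natural[sp$name] <-
      mean(enr$apparent_atom_pct[enr$true_atom_pct == levels[1]])
  }
  out <- list(
    registry = registry, specs = specs, curves = curves,
    natural = data.frame(compound = names(natural),
                         natural_atom_pct = unname(natural),
                         stringsAsFactors = FALSE),
    levels = levels
  )
  .sim_cache[[key]] <- out
  out
}
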