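# Fixtures built in code: simple tubes, forks, and stenosed cases shared
# across the suite.

# single straight vessel of length L mm and radius r mm
make_tube <- function(L = 30, r = 1.5, spacing = 0.5, id = "tube") {
  s <- seq(0, L, by = spacing)
  if (s[length(s)] < L) s <- c(s, L)
  coronary_tree(list(branch(id, s = s, r = rep(r, length(s)))))
}

# parent splitting into two daughters at its tip
make_fork <- function(r_root = 2, r1 = 1.4, r2 = 1.1,
                      L_root = 20, L1 = 25, L2 = 18) {
  sr <- seq(0, L_root, 0.5); s1 <- seq(0, L1, 0.5); s2 <- seq(0, L2, 0.5)
  coronary_tree(list(
    branch("root", s = sr, r = rep(r_root, length(sr))),
    branch("c1", s = s1, r = rep(r1, length(s1)),
           parent_id = "root", attach_s = L_root),
    branch("c2", s = s2, r = rep(r2, length(s2)),
           parent_id = "root", attach_s = L_root)))
}

# closed-form Poiseuille resistance of a uniform tube, mmHg.min/mL
poiseuille_R <- function(L_mm, r_mm, mu = 0.0035) {
  8 * mu * (L_mm * 1e-3) / (pi * (r_mm * 1e-3)^4) / (133.322 / (1e-6 / 60))
}

# a generated tree with a seeded stenosis on its largest first-generation
# daughter; mirrors the study conditions of the synthetic cohort
make_stenosed_case <- function(seed, severity, generations = 2) {
  healthy <- generate_tree(seed = seed, generations = generations)
  kids <- coroflow:::tree_children(healthy)[[healthy$root_id]]
  bid <- kids$id[which.max(vapply(kids$id, function(k)
    healthy$branches[[k]]$samples$r[1], numeric(1)))]
  br <- healthy$branches[[bid]]
  L <- max(br$samples$s)
  len <- min(12, 0.5 * L)
  s_grid <- br$samples$s
  sc <- s_grid[which.min(abs(s_grid - max(len / 2, 0.45 * L)))]
  sten <- stenosis_spec(bid, sc, len, severity)
  list(healthy = healthy, diseased = apply_stenosis(healthy, sten),
       branch_id = bid, stenosis = sten,
       ref_d = 2 * br$samples$r[1],
       site = measurement_site(bid, min(L, sc + len / 2 + 3)),
       patient = patient_record(127, 74, 114))
}

# calibrated FFR at the case's site
case_ffr <- function(tree, case, params = hemo_params(),
                     settings = solver_settings()) {
  bc <- build_outlet_bcs(tree, case$patient, params)
  cal <- calibrate_total_flow(tree, bc$inlet_pressure, bc$bcs,
                              bc$target_flow, settings, params)
  compute_ffrb(cal$solution, bc$inlet_pressure, case$site)$ffrb
}
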