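# Shared fixtures, built once per test run. The calibrated toy trajectory is
# the workhorse for the ensemble/statistics tests.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

toy_sys <- function() memo("sys", make_toy_two_state(44))

toy_model <- function() memo("model", build_model(toy_sys(), eps_O = 3.8))

toy_traj <- function() memo("traj", {
  run_langevin(toy_model(),
               config = simulation_config(n_steps = 4e5, save_stride = 100,
                                          temperature = 300, seed = 5))
})

toy_analysis <- function() memo("analysis", analyze_run(toy_model(), toy_traj()))

toy_angles <- function() memo("angles", pseudodihedrals_frames(toy_traj()$frames))

# brute-force contact enumeration, independent of build_contacts
brute_contacts <- function(structure, cutoff = 8.0, min_sep = 3L) {
  xyz <- structure$xyz
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < min_sep) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  out
}

# fixed-width PDB ATOM record for hand-built parser fixtures
pdb_line <- function(serial, resno, x, y, z, alt = " ", icode = " ",
                     name = "CA", chain = "A", resid = "GLY") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, paste0(" ", name), alt, resid, chain, resno, icode, x, y, z)
}
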