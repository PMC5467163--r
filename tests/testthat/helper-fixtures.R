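# Shared fixtures: all built in code at test time.

# Hand-sized count table with a wild-type member.
toy_count_table <- function(pre = c(WT = 5000, A = 100, B = 200, C = 50),
                            post = c(WT = 20000, A = 400, B = 25, C = 50)) {
  v <- names(pre)
  v[v != "WT"] <- paste0("S", seq_len(sum(v != "WT")), "A")
  structure(data.frame(variant = v,
                       position = ifelse(v == "WT", NA, seq_along(v) - 1L),
                       wt_aa = ifelse(v == "WT", NA, "S"),
                       mut_aa = ifelse(v == "WT", NA, "A"),
                       codon = 1L, replicate = 1L,
                       type = ifelse(v == "WT", "wt", "missense"),
                       pre_count = unname(pre), post_count = unname(post),
                       stringsAsFactors = FALSE),
            class = c("count_table", "data.frame"))
}

# A fitness-table stand-in for specificity tests (Table-style zeta rows).
mock_fit <- function(variant, zeta, label, zeta_lb = -Inf) {
  pv <- parse_variant(variant)
  structure(data.frame(pv, zeta = zeta, stringsAsFactors = FALSE),
            zeta_lb = zeta_lb, label = label,
            class = c("fitness_table", "data.frame"))
}

# End-to-end simulated study in one call.
sim_study <- function(L = 50, seed_lib = 1, seed_dfe = 2, seed_sel = 3,
                      depth = 1e6, g_p = 8, replicates = 1,
                      dfe = list()) {
  spec <- library_spec(L, sequencing_depth_pre = depth,
                       sequencing_depth_post = depth)
  lib <- make_library(spec, seed = seed_lib)
  tspec <- do.call(true_dfe_spec, c(dfe, list(seed = seed_dfe)))
  truth <- sample_true_dfe(lib, tspec)
  cnt <- simulate_selection(lib, truth, selection_scenario(g_p = g_p),
                            seed = seed_sel, replicates = replicates)
  list(lib = lib, truth = truth, counts = cnt, g_wt = attr(cnt, "g_wt"),
       g_p = g_p)
}

# Minimal PDB writer (Calpha + arbitrary named atoms), good enough for
# bio3d::read.pdb.  `atoms` is a data.frame with elety, resid, chain, resno,
# x, y, z.
write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  el <- substr(paste0(atoms$elety, "   "), 1, 3)
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
    seq_len(nrow(atoms)), el, atoms$resid, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, substr(atoms$elety, 1, 1))
  writeLines(c(lines, "END"), path)
  path
}

# Toy homohexamer: one Calpha per queried position in chain A plus six
# symmetric active-site atoms (one per chain) on a circle of given radius.
toy_hexamer <- function(positions_xyz, radius = 10) {
  ang <- seq(0, 2 * pi, length.out = 7L)[1:6]
  act <- data.frame(elety = "SG", resid = "CYS",
                    chain = LETTERS[1:6], resno = 166L,
                    x = radius * cos(ang), y = radius * sin(ang), z = 0)
  ca <- data.frame(elety = "CA", resid = "ALA", chain = "A",
                   resno = positions_xyz$resno,
                   x = positions_xyz$x, y = positions_xyz$y,
                   z = positions_xyz$z)
  rbind(ca, act)
}
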