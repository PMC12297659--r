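# Independent oracles used across tests. These deliberately share no code
# with the package internals they check.

# Direct sliding-window Pearson correlation of a moving map (within a
# boolean mask) against a target, looping over every fully-inside offset.
brute_pearson_scan <- function(mov, tgt, mask) {
  md <- dim(mov); td <- dim(tgt)
  vd <- td - md + 1L
  out <- array(NA_real_, vd)
  a <- mov[mask]
  for (k in seq_len(vd[3])) for (j in seq_len(vd[2])) for (i in seq_len(vd[1])) {
    sub <- tgt[i:(i + md[1] - 1), j:(j + md[2] - 1), k:(k + md[3] - 1)]
    out[i, j, k] <- suppressWarnings(cor(a, sub[mask]))
  }
  out
}

# Kabsch superposition RMSD between two equally sized coordinate sets.
superpose_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((B - A %*% t(R))^2)))
}

# Minimal PDB text for a set of CA-style atoms.
toy_pdb_lines <- function(df) {
  c(sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(df)), paste0(" ", df$atom),
            ifelse(is.null(df$alt), " ", df$alt),
            df$resname, df$chain, df$resno, df$x, df$y, df$z,
            df$occupancy, df$b, df$element),
    "END")
}

# Minimal mmCIF text for the same atoms.
toy_cif_lines <- function(df) {
  tags <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_entity_id",
            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
            "Cartn_z", "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
            "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
                  seq_len(nrow(df)), df$element, df$atom, df$resname,
                  df$chain, df$resno, df$x, df$y, df$z, df$occupancy, df$b,
                  df$resno, df$resname, df$chain, df$atom)
  c("data_toy", "loop_", paste0("_atom_site.", tags), rows)
}

toy_atom_df <- function() {
  data.frame(element = c("N", "C", "C"), chain = "A", resno = 1:3,
             resname = "ALA", atom = c("N", "CA", "C"),
             x = c(11.104, 1.25, -3.5), y = c(6.134, 2.5, 4.75),
             z = c(-6.504, 3.75, 0.125), occupancy = 1, b = 10,
             stringsAsFactors = FALSE)
}

fit_pose_errors <- function(fit_row, truth) {
  q <- as.numeric(fit_row[c("q1", "q2", "q3", "q4")])
  t <- as.numeric(fit_row[c("tx", "ty", "tz")])
  c(rot = quat_angle_deg(q, truth$quaternion),
    trans = sqrt(sum((t - truth$translation)^2)))
}
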