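# Independent oracles and text fixture builders shared across tests.
# Each oracle is coded from first principles, separately from the package
# routines it checks.

# -- torsion oracle: unit plane normals + acos, sign from triple product --
# (the package routine uses a single atan2 form; this one does not)
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- n2 / sqrt(sum(n2^2))
  ang <- acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
  s <- sum(cross(n1, n2) * b2)
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  if (ang == -0) ang <- 0
  ang
}

# -- exhaustive nearest-prototype oracle with loop-based angle wrapping --
oracle_assign_window <- function(window, reference) {
  best_letter <- NA_character_
  best_score <- Inf
  for (letter in sort(rownames(reference))) {
    total <- 0
    for (k in 1:8) {
      d <- window[k] - reference[letter, k]
      while (d > 180) d <- d - 360
      while (d <= -180) d <- d + 360
      total <- total + d^2
    }
    if (total < best_score) {
      best_score <- total
      best_letter <- letter
    }
  }
  best_letter
}

# -- entropy-based Neq coded independently (explicit log base e loop) --
oracle_neq <- function(freq) {
  h <- 0
  for (f in freq) {
    if (f > 0) h <- h - f * log(f)
  }
  exp(h)
}

# -- hand-rolled PDB fixture writer (independent of write_backbone_pdb) --
# atoms: data.frame(record, name, resname, chain, resno, x, y, z,
#                   occ (optional), alt (optional))
fixture_pdb_lines <- function(atoms) {
  occ <- if (is.null(atoms$occ)) rep(1, nrow(atoms)) else atoms$occ
  alt <- if (is.null(atoms$alt)) rep(" ", nrow(atoms)) else atoms$alt
  vapply(seq_len(nrow(atoms)), function(i) {
    name4 <- sprintf(" %-3s", atoms$name[i])
    sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            atoms$record[i], i, name4, alt[i], atoms$resname[i],
            atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0)
  }, character(1))
}

# a well-formed n-residue helical backbone as a PDB atom data.frame
fixture_helix_atoms <- function(n, chain = "A", resno_start = 1L) {
  ch <- build_backbone(phi = rep(-57, n), psi = rep(-47, n),
                       resid = seq(resno_start, length.out = n))
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(record = "ATOM", name = c("N", "CA", "C"),
               resname = "ALA", chain = chain,
               resno = ch$resid[i],
               x = c(ch$N[i, 1], ch$CA[i, 1], ch$C[i, 1]),
               y = c(ch$N[i, 2], ch$CA[i, 2], ch$C[i, 2]),
               z = c(ch$N[i, 3], ch$CA[i, 3], ch$C[i, 3]))
  }))
  rows
}

# minimal PDBx/mmCIF text for the same atom table
fixture_cif_lines <- function(atoms) {
  header <- c(
    "data_fixture", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  body <- vapply(seq_len(nrow(atoms)), function(i) {
    el <- substr(atoms$name[i], 1, 1)
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            atoms$record[i], i, el, atoms$name[i], atoms$resname[i],
            atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i],
            atoms$resno[i], atoms$resname[i], atoms$chain[i],
            atoms$name[i])
  }, character(1))
  c(header, body)
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random rigid transform applied to every coordinate of a backbone_chain
apply_rigid <- function(chain, angles, translation) {
  rx <- matrix(c(1, 0, 0,
                 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[2]), -sin(angles[2]), 0,
                 sin(angles[2]), cos(angles[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% rz
  tr <- function(m) sweep(m %*% t(rot), 2, translation, `+`)
  backbone_chain(chain$resid, chain$resname,
                 tr(chain$N), tr(chain$CA), tr(chain$C),
                 label = chain$label)
}

# four designed uniform-window states whose central letters are m, d, i, a
four_state_angles <- function() {
  rbind(c(-57, -47), c(-120, 135), c(-30, 90), c(120, 30))
}
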